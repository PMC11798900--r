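test_that("newick parsing round-trips and rejects malformed input", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(1, 1))
  t27 <- simulate_tree(27, 1, seed = 5)
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(t27, tmp)
  back <- read_newick(tmp, file = TRUE)
  expect_setequal(back$tip.label, t27$tip.label)
  lab <- sort(t27$tip.label)
  expect_equal(shared_path_matrix(back)[lab, lab],
               shared_path_matrix(t27)[lab, lab], tolerance = 1e-9)
  # idempotence of parse -> write -> parse
  expect_identical(ape::write.tree(back), ape::write.tree(t27))
  expect_error(read_newick("((A:1,B:1"), class = "grasshydro_parse_error")
  unlink(tmp)
})

test_that("Brownian covariance carries shared path lengths and the lambda
           transform", {
  tr <- read_newick("((A:1,B:1):1,C:2):0;")
  V1 <- bm_covariance(tr, 1)
  expect_equal(unname(V1[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  V0 <- bm_covariance(tr, 0)
  expect_true(all(V0[upper.tri(V0)] == 0))
  expect_equal(diag(V0), diag(V1)) # diagonal untransformed
  expect_error(bm_covariance(tr, 1.2),
               class = "grasshydro_invalid_parameter")
  # vs the ape oracle on a random ultrametric tree
  t40 <- simulate_tree(40, 1, seed = 11)
  expect_equal(shared_path_matrix(t40),
               ape::vcv(t40)[t40$tip.label, t40$tip.label],
               tolerance = 1e-10)
  expect_lt(diff(range(diag(shared_path_matrix(t40)))), 1e-9) # ultrametric
})

test_that("PGLS reduces to OLS on star trees and at lambda zero", {
  set.seed(21)
  star <- ape::stree(15, "star")
  star$edge.length <- rep(1.7, 15)
  x <- rnorm(15)
  y <- 1 + 2 * x + rnorm(15)
  names(x) <- names(y) <- star$tip.label
  ols <- unname(coef(lm(y ~ x)))
  f_star <- pgls_fit(y, x, star, lambda = 1)
  expect_lt(max(abs(unname(f_star$coefficients) - ols)), 1e-9)
  t15 <- simulate_tree(15, 1, seed = 3)
  names(x) <- names(y) <- t15$tip.label
  f0 <- pgls_fit(y, x, t15, lambda = 0)
  expect_lt(max(abs(unname(f0$coefficients) - ols)), 1e-9)
  # p-values at lambda = 0 equal the OLS t-test
  ols_p <- summary(lm(y ~ x))$coefficients[, 4]
  expect_equal(unname(f0$p_value), unname(ols_p), tolerance = 1e-9)
})

test_that("PGLS with fixed lambda matches the nlme/corPagel oracle", {
  t30 <- simulate_tree(30, 1, seed = 13)
  set.seed(14)
  x <- drop(simulate_bm(t30, 1))
  y <- 0.5 + 1.5 * x + drop(simulate_bm(t30, 0.6))
  d <- data.frame(x = x, y = y, sp = t30$tip.label)
  for (lam in c(0.3, 0.8, 1)) {
    g <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(lam, t30, fixed = TRUE,
                                               form = ~sp))
    mine <- pgls_fit(setNames(y, t30$tip.label),
                     setNames(x, t30$tip.label), t30, lambda = lam)
    expect_equal(unname(mine$coefficients), unname(coef(g)),
                 tolerance = 1e-6)
  }
})

test_that("maximum-likelihood lambda tracks the phytools estimator", {
  t80 <- simulate_tree(80, 1, seed = 15)
  set.seed(16)
  y <- drop(simulate_bm(t80, 1))
  mine <- pgls_fit(setNames(y, t80$tip.label),
                   matrix(1, 80, 1, dimnames = list(t80$tip.label, "i")),
                   t80, lambda = "ML")
  ph <- phytools::phylosig(t80, setNames(y, t80$tip.label),
                           method = "lambda")
  expect_equal(mine$lambda, ph$lambda, tolerance = 0.02)
  # likelihood at the optimum is at least the boundary likelihoods
  prof <- mine$profile
  expect_gte(mine$loglik + 1e-8, prof$loglik[1])
  expect_gte(mine$loglik + 1e-8, prof$loglik[nrow(prof)])
})

test_that("PGLS recovers a known regression slope under Brownian errors", {
  t60 <- simulate_tree(60, 1, seed = 17)
  slopes <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- drop(simulate_bm(t60, 1))
    y <- 2 * x + drop(simulate_bm(t60, 0.5))
    pgls_fit(setNames(y, t60$tip.label), setNames(x, t60$tip.label),
             t60)$coefficients[2]
  })
  expect_lt(abs(mean(slopes) - 2), 0.1)
})

test_that("phylogenetic ANOVA reproduces hand-computed F and respects the
           simulation p floor", {
  t6 <- simulate_tree(6, 1, seed = 2)
  a <- phylo_anova(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2), t6,
                   n_sim = 199, seed = 1)
  expect_equal(a$F_obs, 13.5, tolerance = 1e-12)
  # cross-check F against stats::aov
  f_aov <- summary(stats::aov(c(1, 2, 3, 4, 5, 6) ~
                                factor(c(1, 1, 1, 2, 2, 2))))[[1]]$F[1]
  expect_equal(a$F_obs, f_aov, tolerance = 1e-9)
  # a 10-SD effect on a star tree attains the minimum p
  star <- ape::stree(20, "star")
  star$edge.length <- rep(1, 20)
  g <- rep(c("a", "b"), each = 10)
  y <- ifelse(g == "a", 0, 10) + rnorm(20, 0, 1)
  names(y) <- star$tip.label
  a2 <- phylo_anova(y, g, star, n_sim = 999, seed = 2)
  expect_equal(a2$p_phylo, 1 / 1000)
  expect_error(phylo_anova(rep(1, 6), c(1, 1, 1, 2, 2, 2), t6),
               class = "grasshydro_degenerate_data")
  expect_error(phylo_anova(y, rep("a", 20), star),
               class = "grasshydro_invalid_grouping")
})

test_that("the PGLS-based parametric ANOVA variant detects the same
           contrast", {
  d <- generate_dataset(exact_config(n_species = 30, n_c4_origins = 6,
                                     seed = 9))
  tr <- d$traits
  a <- phylo_anova(setNames(tr$gs, tr$species),
                   setNames(tr$pathway, tr$species), d$tree,
                   method = "pgls")
  expect_lt(a$p_phylo, 1e-6) # noise-free twofold contrast
})

test_that("phylogenetic RMA keeps the RMA identities and the star-tree
           limit", {
  t25 <- simulate_tree(25, 1, seed = 19)
  set.seed(20)
  x <- drop(simulate_bm(t25, 1))
  names(x) <- t25$tip.label
  y2 <- 2 * x
  expect_equal(prma_fit(x, y2, t25, lambda = 1)$slope, 2, tolerance = 1e-9)
  y <- 1.2 * x + drop(simulate_bm(t25, 0.4))
  names(y) <- t25$tip.label
  fxy <- prma_fit(x, y, t25, lambda = 1)
  fyx <- prma_fit(y, x, t25, lambda = 1)
  expect_equal(fxy$slope * fyx$slope, 1, tolerance = 1e-9)
  # star tree: classical RMA via the direct SD-ratio formula
  star <- ape::stree(25, "star")
  star$edge.length <- rep(1, 25)
  names(x) <- names(y) <- star$tip.label
  cls <- sign(cor(x, y)) * sd(y) / sd(x)
  expect_equal(prma_fit(x, y, star, lambda = 1)$slope, cls,
               tolerance = 1e-9)
  expect_error(prma_fit(rep(1, 25), y, star),
               class = "grasshydro_degenerate_data")
})

test_that("Pearson correlation matches the hand-computed t statistic", {
  # construct a 10-point fixture with r exactly 0.8
  set.seed(30)
  raw_x <- rnorm(10)
  raw_z <- rnorm(10)
  x <- (raw_x - mean(raw_x)) / sd(raw_x)
  z <- residuals(lm(raw_z ~ x))
  z <- z / sd(z)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * z
  ct <- correlation_test(x, y)
  expect_equal(ct$r, 0.8, tolerance = 1e-9)
  expect_equal(ct$t, 0.8 * sqrt(8 / 0.36), tolerance = 1e-9)
  # collinear and orthogonal limits
  expect_equal(correlation_test(x, 3 * x)$r, 1, tolerance = 1e-12)
  expect_gt(correlation_test(x, 3 * x)$p, 0) # underflow clamped, not zero
  expect_lt(abs(correlation_test(x, z)$r), 1e-12)
  expect_error(correlation_test(x, rep(1, 10)),
               class = "grasshydro_degenerate_data")
})

test_that("the injected supply:demand contrast is detected with high power", {
  hits <- sapply(1:50, function(s) {
    cfg <- synthetic_config(n_species = 50, n_c4_origins = 8,
                            pathway_fold_effects = c(gs = 0.5, kleaf = 1,
                                                     aarea = 1.6, dv = 1.8),
                            bm_sigma = 0, lognormal_cv = 0.2,
                            seed = 5000 + s)
    tree <- simulate_tree(50, 1, seed = cfg$seed)
    pw <- assign_pathways(tree, 8, seed = cfg$seed + 1)
    tt <- simulate_traits(tree, pw, cfg)
    a <- phylo_anova(setNames(tt$kleaf_gs, tt$species),
                     setNames(tt$pathway, tt$species), tree,
                     n_sim = 199, seed = cfg$seed + 2)
    a$p_phylo < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("comparative regression table covers pairs, subsets and methods", {
  d <- generate_dataset(synthetic_config(n_species = 30, n_c4_origins = 6,
                                         seed = 31))
  regs <- comparative_regressions(d$traits, d$tree)
  expect_true(all(c("PGLS", "PRMA", "Pearson") %in% regs$method))
  expect_true(all(regs$subset %in% c("all", "C3", "C4")))
  expect_true(all(is.finite(regs$estimate)))
})
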