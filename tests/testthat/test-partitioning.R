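test_that("outside-xylem conductance inverts the series sum", {
  expect_equal(outside_xylem_conductance(5, 10), 10)
  expect_equal(outside_xylem_conductance(7, 9), 31.5)
  expect_equal(combine_series(9, 31.5), 7)
  # K_xc -> infinity: K_oxc -> K_leaf
  expect_equal(outside_xylem_conductance(5, 1e12), 5, tolerance = 1e-9)
  expect_error(outside_xylem_conductance(5, 4),
               class = "grasshydro_infeasible_partition")
  expect_error(outside_xylem_conductance(5, 5),
               class = "grasshydro_infeasible_partition")
})

test_that("series recombination recovers K_leaf across random valid pairs", {
  set.seed(7)
  k_leaf <- runif(1000, 0.1, 30)
  k_xc <- k_leaf * (1 + runif(1000, 1e-3, 50))
  k_oxc <- outside_xylem_conductance(k_leaf, k_xc)
  expect_true(all(abs(combine_series(k_xc, k_oxc) - k_leaf) / k_leaf < 1e-9))
})

test_that("vulnerability fit recovers noiseless lines exactly", {
  cv <- data.frame(psi = seq(0, -2, length.out = 6),
                   kleaf = 10 + 5 * seq(0, -2, length.out = 6))
  f <- fit_vulnerability(cv)
  expect_equal(f$K_max, 10, tolerance = 1e-12)
  expect_equal(f$slope, 5, tolerance = 1e-12)
  expect_equal(f$P50, -1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # P50 identity against the generator's closed form (line stays positive
  # over the sampled range, so no truncation distorts the fit)
  g <- generate_vulnerability_curve(12, 4, 0, 6, seed = 1)
  expect_equal(fit_vulnerability(g)$P50, -12 / (2 * 4), tolerance = 1e-12)
})

test_that("non-declining curves yield the no-decline signal", {
  flat <- data.frame(psi = c(0, -1, -2), kleaf = c(5, 5, 5))
  f <- fit_vulnerability(flat)
  expect_false(f$declines)
  expect_true(is.na(f$P50))
  rising <- data.frame(psi = c(0, -1, -2), kleaf = c(5, 6, 7))
  expect_false(fit_vulnerability(rising)$declines)
  expect_error(fit_vulnerability(flat[1:2, ]),
               class = "grasshydro_invalid_parameter")
})

test_that("mean fitted P50 from noisy replicate curves stays within 5% of
           truth", {
  p50 <- sapply(1:200, function(s) {
    cv <- generate_vulnerability_curve(12, 4, noise_sd = 0.5, n_points = 10,
                                       seed = s)
    fit_vulnerability(cv)$P50
  })
  expect_lt(abs(mean(p50) - (-1.5)) / 1.5, 0.05)
})

test_that("SMA slope option differs from OLS on noisy data but matches on
           exact lines", {
  g <- generate_vulnerability_curve(12, 4, 0, 8, seed = 2)
  expect_equal(fit_vulnerability(g, method = "sma")$slope,
               fit_vulnerability(g)$slope, tolerance = 1e-9)
  gn <- generate_vulnerability_curve(12, 4, 1, 20, seed = 3)
  expect_gt(fit_vulnerability(gn, method = "sma")$slope,
            fit_vulnerability(gn)$slope)
})

test_that("trait ratios are computed row-wise in conventional units", {
  tt <- data.frame(species = c("a", "b", "c"),
                   kleaf = c(10, 8, 6), gs = c(0.2, 0.15, -1),
                   aarea = c(30, 30, 30))
  out <- trait_ratios(tt)
  expect_equal(out$kleaf_gs[1], 50)
  expect_equal(out$wue_i[2], 200)
  expect_true(is.na(out$kleaf_gs[3]))
  expect_true(out$ratio_flag[3])
  expect_false(out$ratio_flag[1])
})

test_that("species means aggregate across studies with ratio gating", {
  rec <- data.frame(
    species = c("a", "a", "b", "b", "c", "c"),
    study = c("s1", "s2", "s1", "s2", "s1", "s2"),
    pathway = "C3",
    trait = c("kleaf", "kleaf", "kleaf", "gs", "gs", "kleaf"),
    value = c(8, 12, 10, 0.2, 0.3, 6))
  out <- aggregate_species_means(rec)
  expect_equal(out$kleaf[out$species == "a"], 10)
  # b: kleaf and gs in different studies? s1 has kleaf, s2 has gs -> no ratio
  expect_true(is.na(out$kleaf_gs[out$species == "b"]))
  # c likewise
  expect_true(is.na(out$kleaf_gs[out$species == "c"]))
  # single study with both traits -> ratio from species means
  rec2 <- rbind(rec, data.frame(species = "b", study = "s3", pathway = "C3",
                                trait = c("kleaf", "gs"),
                                value = c(14, 0.4)))
  out2 <- aggregate_species_means(rec2)
  expect_equal(out2$kleaf_gs[out2$species == "b"],
               mean(c(10, 14)) / mean(c(0.2, 0.4)))
  # conflicting pathway labels are a consistency error
  rec$pathway[1] <- "C4"
  expect_error(aggregate_species_means(rec),
               class = "grasshydro_consistency_error")
})

test_that("pathway fold differences report C4 as percent of C3 and are
           scale-equivariant", {
  tt <- data.frame(pathway = rep(c("C3", "C4"), each = 3),
                   gs = c(0.3, 0.3, 0.3, 0.087, 0.087, 0.087))
  fd <- pathway_fold_differences(tt, "gs")
  expect_equal(fd$pct_of_c3, 29)
  tt$gs <- tt$gs * 1000
  expect_equal(pathway_fold_differences(tt, "gs")$pct_of_c3, 29)
  same <- data.frame(pathway = c("C3", "C3", "C4"), x = c(2, 4, 3))
  expect_equal(pathway_fold_differences(same, "x")$pct_of_c3, 100)
  only3 <- data.frame(pathway = c("C3", "C3"), x = 1:2)
  expect_error(pathway_fold_differences(only3, "x"),
               class = "grasshydro_contrast_undefined")
})

test_that("noise-free generator contrasts round-trip exactly through the
           fold statistics", {
  d <- generate_dataset(exact_config())
  fd <- pathway_fold_differences(d$traits,
                                 trait_cols = c("gs", "kleaf", "aarea",
                                                "dv", "kleaf_gs"))
  expect_equal(fd$pct_of_c3[fd$trait == "gs"], 50, tolerance = 1e-12)
  expect_equal(fd$pct_of_c3[fd$trait == "kleaf"], 100, tolerance = 1e-12)
  expect_equal(fd$pct_of_c3[fd$trait == "aarea"], 160, tolerance = 1e-12)
  expect_equal(fd$pct_of_c3[fd$trait == "dv"], 180, tolerance = 1e-12)
  expect_equal(fd$pct_of_c3[fd$trait == "kleaf_gs"], 200, tolerance = 1e-12)
})

test_that("Dixon's Q flags the documented outlier cases", {
  d <- dixon_outlier_test(c(1.0, 1.1, 1.2, 5.0))
  expect_equal(d$Q, 3.8 / 4.0)
  expect_equal(d$critical, 0.829)
  expect_true(d$flagged)
  expect_equal(d$outlier_value, 5.0)
  expect_false(dixon_outlier_test(c(1, 2, 3, 4, 5))$flagged)
  expect_error(dixon_outlier_test(c(1, 2)),
               class = "grasshydro_invalid_parameter")
  expect_error(dixon_outlier_test(rep(2, 5)),
               class = "grasshydro_degenerate_data")
})

test_that("Dixon's Q agrees with brute-force gap/range over permutations", {
  vals <- c(2.1, 2.3, 2.4, 2.5, 7.0)
  brute <- function(v) {
    s <- sort(v)
    n <- length(s)
    max((s[2] - s[1]), (s[n] - s[n - 1])) / (s[n] - s[1])
  }
  for (i in 1:20) {
    p <- sample(vals)
    expect_equal(dixon_outlier_test(p)$Q, brute(p))
  }
})

test_that("partition profile joins traits with anatomy and flags infeasible
           rows", {
  hyd <- data.frame(species = c("a", "b"), K_xc = c(20, 4))
  tt <- data.frame(species = c("a", "b"), kleaf = c(5, 5))
  out <- partition_profile(tt, hyd)
  expect_equal(out$K_oxc[out$species == "a"],
               outside_xylem_conductance(5, 20))
  expect_true(is.na(out$K_oxc[out$species == "b"]))
  expect_false(out$partition_ok[out$species == "b"])
})
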