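# Phylogenetic comparative statistics implemented from first principles:
# Brownian-motion covariance from shared path lengths, Pagel's lambda by
# maximum likelihood (grid + golden-section refinement), PGLS, a
# simulation-based phylogenetic ANOVA, phylogenetic reduced major axis
# regression, and plain Pearson correlation tests. ape is used for tree
# handling only; the covariance and the estimators are computed here.

#' Parse a newick string or file into a phylogeny
#'
#' Thin wrapper over the ape parser that fails loudly on malformed input and
#' guarantees unique tip labels.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Read from a file instead of a literal string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text, file = FALSE) {
  tr <- tryCatch(
    if (file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop(errorCondition(paste0("malformed newick input: ",
                               substr(if (file) text else text, 1, 60)),
                        class = c("grasshydro_parse_error",
                                  "grasshydro_error")))
  }
  if (anyDuplicated(tr$tip.label)) {
    stop(errorCondition("duplicate tip labels",
                        class = c("grasshydro_parse_error",
                                  "grasshydro_error")))
  }
  tr
}

# Shared root-to-MRCA path lengths between all tip pairs, computed by a
# single post-order sweep: node depths from the root plus, at every internal
# node, the tip pairs split between its child subtrees share exactly that
# node's depth.
shared_path_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)
  # parents precede children in a preorder of the edge list
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(eo$edge)))) {
    depth[eo$edge[i, 2]] <- depth[eo$edge[i, 1]] + eo$edge.length[i]
  }
  V <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(ntip)]
  tips_below <- vector("list", nnode)
  for (t in seq_len(ntip)) tips_below[[t]] <- t
  for (i in seq_len(nrow(eo$edge))) { # postorder: children before parents
    par <- eo$edge[i, 1]; child <- eo$edge[i, 2]
    a <- tips_below[[par]]; b <- tips_below[[child]]
    if (length(a) && length(b)) {
      V[a, b] <- depth[par]
      V[b, a] <- depth[par]
    }
    tips_below[[par]] <- c(a, b)
  }
  V
}

#' Brownian-motion covariance with Pagel's lambda
#'
#' V[i,j] = lambda * (shared root-to-MRCA path length) for i != j and
#' V[i,i] = root-to-tip depth of tip i (the diagonal is untransformed).
#' lambda = 0 removes all phylogenetic covariance; lambda = 1 is plain
#' Brownian motion.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param lambda Pagel's lambda in [0, 1].
#' @return Tip-by-tip covariance matrix (unit Brownian rate).
#' @export
bm_covariance <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop_invalid("lambda must be in [0, 1]")
  V <- shared_path_matrix(tree)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  V
}

# Gaussian log-likelihood of y ~ N(X beta, sigma2 V), profiled over beta and
# sigma2 (full ML).
gls_profile_loglik <- function(y, X, V) {
  n <- length(y)
  L <- chol(V)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -n / 2 * log(2 * pi) - sum(log(diag(L))) - n / 2 * log(sigma2) - n / 2
  list(loglik = ll, beta = fit$coefficients, sigma2 = sigma2, rss = rss,
       L = L, Xs = Xs, ys = ys)
}

# ML lambda on a 201-point grid over [0,1], refined by golden-section search
# in the bracketing interval; interior values win ties with boundaries when
# the log-likelihood difference is below 1e-6.
estimate_lambda <- function(y, X, tree) {
  V0 <- shared_path_matrix(tree)
  d0 <- diag(V0)
  Vfun <- function(lam) {
    V <- V0 * lam
    diag(V) <- d0
    V
  }
  ll <- function(lam) gls_profile_loglik(y, X, Vfun(lam))$loglik
  grid <- seq(0, 1, length.out = 201)
  lls <- vapply(grid, ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lam <- opt$maximum; best <- opt$objective
  # explicit boundary comparison: never report a boundary when an interior
  # value is effectively as good
  for (bnd in c(0, 1)) {
    if (lls[ifelse(bnd == 0, 1, 201)] > best + 1e-6) {
      lam <- bnd; best <- lls[ifelse(bnd == 0, 1, 201)]
    }
  }
  list(lambda = lam, loglik = best,
       profile = data.frame(lambda = grid, loglik = lls))
}

#' Phylogenetic generalized least squares
#'
#' Fits y = X beta + e with e ~ N(0, sigma2 V(lambda)), where V(lambda) is
#' the lambda-scaled Brownian covariance of the tree. beta is the GLS
#' estimator at the maximum-likelihood lambda (full Gaussian likelihood,
#' profiled over beta and sigma2); coefficient tests are t-statistics with
#' n - k degrees of freedom. On a star phylogeny, or at lambda = 0, the fit
#' reduces to ordinary least squares.
#'
#' @param y Response vector, named by species or ordered as `tree$tip.label`.
#' @param X Design matrix (with intercept column), or a vector treated as a
#'   single predictor to which an intercept is added.
#' @param tree An `ape::phylo` tree.
#' @param lambda `"ML"` (default) or a fixed value in [0, 1].
#' @return List of class `pgls_fit`: `coefficients`, `se`, `t`, `p_value`,
#'   `lambda`, `loglik`, `sigma2`, `r_squared`, `n`, `df_residual`,
#'   `profile` (lambda log-likelihood profile when estimated).
#' @export
pgls_fit <- function(y, X, tree, lambda = "ML") {
  if (is.null(dim(X))) {
    nms <- names(X)
    X <- cbind(`(Intercept)` = 1, x = X)
    rownames(X) <- nms
  }
  X <- as.matrix(X)
  if (is.null(rownames(X)) && !is.null(names(y))) rownames(X) <- names(y)
  y <- align_to_tips(y, tree)
  X <- X[align_index(rownames(X), tree, nrow(X)), , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  if (qr(X)$rank < k) {
    stop(errorCondition("singular design matrix",
                        class = c("grasshydro_rank_error",
                                  "grasshydro_error")))
  }
  profile <- NULL
  if (identical(lambda, "ML")) {
    est <- estimate_lambda(y, X, tree)
    lambda <- est$lambda
    profile <- est$profile
  }
  V <- bm_covariance(tree, lambda)
  g <- gls_profile_loglik(y, X, V)
  sigma2_u <- g$rss / (n - k) # unbiased, for coefficient tests
  XtX_inv <- chol2inv(chol(crossprod(g$Xs)))
  se <- sqrt(diag(XtX_inv) * sigma2_u)
  tval <- g$beta / se
  pval <- 2 * pt(abs(tval), df = n - k, lower.tail = FALSE)
  # GLS R^2 against the intercept-only model under the same V
  g0 <- gls_profile_loglik(y, matrix(1, n, 1), V)
  r2 <- 1 - g$rss / g0$rss
  structure(list(coefficients = setNames(g$beta, colnames(X)), se = se,
                 t = tval, p_value = pval, lambda = lambda,
                 loglik = g$loglik, sigma2 = g$sigma2, r_squared = r2,
                 n = n, df_residual = n - k, profile = profile),
            class = "pgls_fit")
}

align_index <- function(nms, tree, n) {
  if (is.null(nms)) {
    if (n != length(tree$tip.label)) {
      stop_invalid("unnamed data must match the number of tips")
    }
    return(seq_len(n))
  }
  if (!all(tree$tip.label %in% nms)) {
    stop_invalid("data names do not cover all tip labels")
  }
  match(tree$tip.label, nms)
}

align_to_tips <- function(y, tree) {
  idx <- align_index(names(y), tree, length(y))
  unname(y[idx])
}

# One-way ANOVA F statistics, vectorised over the columns of Y.
anova_f_columns <- function(Y, groups) {
  g <- as.factor(groups)
  n <- nrow(Y)
  k <- nlevels(g)
  ng <- as.numeric(table(g))
  tot <- colSums(Y)
  sst <- colSums(Y^2) - tot^2 / n
  gs <- rowsum(Y, g)
  ssb <- colSums(gs^2 / ng) - tot^2 / n
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Cholesky factor (lower) of the tree's BM covariance; cached by callers.
bm_chol <- function(tree, lambda = 1) t(chol(bm_covariance(tree, lambda)))

#' Simulate Brownian-motion traits on a tree
#'
#' @param tree An `ape::phylo` tree.
#' @param sigma Brownian rate (standard deviation per unit branch length).
#' @param n Number of independent replicate traits.
#' @return Matrix (tips x n) of trait values (root state 0), rows named by
#'   tip label.
#' @export
simulate_bm <- function(tree, sigma = 1, n = 1) {
  L <- bm_chol(tree)
  ntip <- length(tree$tip.label)
  out <- L %*% matrix(rnorm(ntip * n), ntip, n) * sigma
  rownames(out) <- tree$tip.label
  out
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed statistic is the standard one-way ANOVA F. Its null
#' distribution is generated by simulating Brownian motion along the tree
#' (rate estimated from the data, though F is scale-free) with the group
#' labels held fixed, so the test asks whether the group contrast exceeds
#' what shared ancestry alone produces. p = (1 + #\{F_sim >= F_obs\}) /
#' (n_sim + 1).
#'
#' @param trait Numeric vector, named by species or in tip order.
#' @param groups Group labels (same order as `trait`).
#' @param tree An `ape::phylo` tree.
#' @param n_sim Number of Brownian null simulations.
#' @param seed Optional RNG seed for the null simulations.
#' @param method `"simulation"` (default) or `"pgls"` (parametric variant:
#'   PGLS on a group indicator, reporting the indicator's t-test).
#' @return List with `F_obs`, `p_phylo`, `n_sim`, `method` (simulation) or
#'   the indicator coefficient, `t`, `p_phylo` (pgls).
#' @export
phylo_anova <- function(trait, groups, tree, n_sim = 1000, seed = NULL,
                        method = c("simulation", "pgls")) {
  method <- match.arg(method)
  trait <- align_to_tips(trait, tree)
  groups <- if (!is.null(names(groups))) {
    groups[match(tree$tip.label, names(groups))]
  } else groups
  g <- as.factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 1)) {
    stop(errorCondition("need >= 2 non-empty groups",
                        class = c("grasshydro_invalid_grouping",
                                  "grasshydro_error")))
  }
  if (sd(trait) == 0) {
    stop(errorCondition("trait is constant: F undefined",
                        class = c("grasshydro_degenerate_data",
                                  "grasshydro_error")))
  }
  if (method == "pgls") {
    X <- stats::model.matrix(~g)
    rownames(X) <- tree$tip.label
    fit <- pgls_fit(setNames(trait, tree$tip.label), X, tree)
    return(list(coefficient = fit$coefficients[2], t = fit$t[2],
                p_phylo = fit$p_value[2], lambda = fit$lambda,
                method = "pgls"))
  }
  F_obs <- anova_f_columns(matrix(trait, ncol = 1), g)
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate_bm(tree, sigma = 1, n = n_sim)
  F_sim <- anova_f_columns(sims, g)
  p <- (1 + sum(F_sim >= F_obs)) / (n_sim + 1)
  list(F_obs = unname(F_obs), p_phylo = p, n_sim = n_sim,
       method = "simulation")
}

#' Phylogenetic reduced major axis regression
#'
#' RMA under the phylogenetic covariance: variables are centred on their GLS
#' (phylogenetically weighted) means, variances and covariance computed in
#' the V(lambda)^-1 metric, the slope is sign(cov) * sqrt(var_y/var_x), and
#' the intercept passes through the GLS means. On a star tree this is the
#' classical ahistorical RMA.
#'
#' @param x,y Numeric vectors, named by species or in tip order.
#' @param tree An `ape::phylo` tree.
#' @param lambda `"ML"` (estimated from the residuals of y on x) or fixed.
#' @return List with `slope`, `intercept`, `r`, `lambda`.
#' @export
prma_fit <- function(x, y, tree, lambda = 1) {
  x <- align_to_tips(x, tree)
  y <- align_to_tips(y, tree)
  if (identical(lambda, "ML")) {
    lambda <- pgls_fit(setNames(y, tree$tip.label),
                       cbind(1, x = x), tree)$lambda
  }
  V <- bm_covariance(tree, lambda)
  n <- length(x)
  L <- chol(V)
  one <- backsolve(L, rep(1, n), transpose = TRUE)
  xs <- backsolve(L, x, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  mx <- sum(one * xs) / sum(one^2)
  my <- sum(one * ys) / sum(one^2)
  dx <- xs - one * mx
  dy <- ys - one * my
  vx <- sum(dx^2) / (n - 1)
  vy <- sum(dy^2) / (n - 1)
  if (vx == 0) {
    stop(errorCondition("zero variance in x after transformation",
                        class = c("grasshydro_degenerate_data",
                                  "grasshydro_error")))
  }
  cxy <- sum(dx * dy) / (n - 1)
  r <- cxy / sqrt(vx * vy)
  slope <- sign(if (cxy == 0) 1 else cxy) * sqrt(vy / vx)
  list(slope = slope, intercept = my - slope * mx, r = r, lambda = lambda)
}

#' Pearson correlation with t-based significance
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return List with `r`, `p`, `t`, `df`, `n`.
#' @export
correlation_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop(errorCondition("zero variance",
                        class = c("grasshydro_degenerate_data",
                                  "grasshydro_error")))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = max(ct$p.value, .Machine$double.xmin),
       t = unname(ct$statistic), df = unname(ct$parameter), n = n)
}

# Log-transform rule shared by the regression table: strictly positive
# traits spanning more than one order of magnitude are fitted on log scale
# (power-law form), unless disabled.
should_log <- function(x) {
  x <- x[is.finite(x)]
  length(x) > 0 && all(x > 0) && max(x) / min(x) > 10
}

#' Pairwise comparative regressions for a trait table
#'
#' For each requested response~predictor pair and species subset (all, C3,
#' C4), fits PGLS (ML lambda), PRMA and the Pearson correlation. Traits that
#' are strictly positive and span more than an order of magnitude are
#' log-transformed first (power-law fits) unless `log_transform = FALSE`.
#'
#' @param traits `data.frame` with `species`, `pathway` and trait columns.
#' @param tree Tree covering the species.
#' @param pairs 2-column character matrix (response, predictor); defaults to
#'   gas-exchange vs hydraulics pairs present in the table.
#' @param subsets Character vector among `"all"`, `"C3"`, `"C4"`.
#' @param log_transform Apply the automatic log rule.
#' @return `data.frame` with one row per pair x subset x method.
#' @export
comparative_regressions <- function(traits, tree, pairs = NULL,
                                    subsets = c("all", "C3", "C4"),
                                    log_transform = TRUE) {
  if (is.null(pairs)) {
    cand <- rbind(c("gs", "kleaf"), c("aarea", "gs"), c("aarea", "kleaf"))
    pairs <- cand[cand[, 1] %in% names(traits) &
                    cand[, 2] %in% names(traits), , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    resp <- pairs[i, 1]; pred <- pairs[i, 2]
    for (sub in subsets) {
      d <- if (sub == "all") traits else traits[traits$pathway == sub, ]
      d <- d[is.finite(d[[resp]]) & is.finite(d[[pred]]), ]
      if (nrow(d) < 4) next
      tr <- ape::keep.tip(tree, intersect(tree$tip.label, d$species))
      d <- d[match(tr$tip.label, d$species), ]
      y <- d[[resp]]; x <- d[[pred]]
      if (log_transform && should_log(y)) y <- log(y)
      if (log_transform && should_log(x)) x <- log(x)
      names(y) <- names(x) <- d$species
      pg <- pgls_fit(y, x, tr)
      pr <- prma_fit(x, y, tr, lambda = pg$lambda)
      ct <- correlation_test(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        response = resp, predictor = pred, subset = sub,
        method = c("PGLS", "PRMA", "Pearson"),
        estimate = c(unname(pg$coefficients[2]), pr$slope, ct$r),
        lambda = c(pg$lambda, pr$lambda, NA),
        p = c(pg$p_value[2], NA, ct$p), n = nrow(d))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
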