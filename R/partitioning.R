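# Partitioning leaf hydraulic conductance into xylem and outside-xylem
# components, vulnerability fits, trait ratios, species-mean aggregation,
# pathway contrasts, and small-sample outlier screening.

#' Outside-xylem conduit conductance
#'
#' The xylem and outside-xylem pathways act in series within the leaf:
#' 1/K_leaf = 1/K_xc + 1/K_oxc. Given measured K_leaf and anatomy-derived
#' K_xc, the outside-xylem component is K_oxc = (1/K_leaf - 1/K_xc)^-1.
#'
#' @param k_leaf Leaf hydraulic conductance, mmol m^-2 s^-1 MPa^-1
#'   (vectorised).
#' @param k_xc Theoretical xylem conduit conductance, same units.
#' @return K_oxc, same units.
#' @examples
#' outside_xylem_conductance(5, 10) # 10: equal-resistance split
#' @export
outside_xylem_conductance <- function(k_leaf, k_xc) {
  check_positive(k_leaf, "k_leaf")
  check_positive(k_xc, "k_xc")
  if (any(k_xc <= k_leaf)) {
    stop(errorCondition(
      "K_xc <= K_leaf: series partition infeasible (outside-xylem resistance would be <= 0)",
      class = c("grasshydro_infeasible_partition", "grasshydro_error")))
  }
  1 / (1 / k_leaf - 1 / k_xc)
}

#' Series combination of two conductances
#'
#' @param k1,k2 Conductances (vectorised).
#' @return Combined series conductance (1/k1 + 1/k2)^-1.
#' @export
combine_series <- function(k1, k2) 1 / (1 / k1 + 1 / k2)

#' Fit a linear hydraulic vulnerability curve
#'
#' Fits K_leaf = K_max + slope * Psi_leaf by ordinary least squares (the
#' linear form approximates the decline of grass K_leaf at high water
#' potentials well). P50 is the water potential at which the fitted line has
#' declined to half its y-intercept: P50 = -K_max / (2 slope). A standardised
#' major axis variant is available for sensitivity analysis.
#'
#' @param curve `data.frame` with columns `psi` (MPa, <= 0) and `kleaf`
#'   (conductance, >= 0); at least 3 points with non-constant `psi`.
#' @param method `"ols"` (default) or `"sma"`.
#' @return List of class `vulnerability_fit`: `K_max` (intercept), `slope`
#'   (positive when conductance declines as Psi falls), `P50`, `r_squared`,
#'   `p_value`, `n`, `method`, `declines` (FALSE when the fitted slope is
#'   <= 0, in which case `P50` is `NA`).
#' @examples
#' cv <- data.frame(psi = c(0, -1, -2), kleaf = c(10, 5, 0))
#' fit_vulnerability(cv)$P50 # -1
#' @export
fit_vulnerability <- function(curve, method = c("ols", "sma")) {
  method <- match.arg(method)
  if (!all(c("psi", "kleaf") %in% names(curve))) {
    stop_schema("vulnerability curve needs columns psi, kleaf")
  }
  curve <- curve[is.finite(curve$psi) & is.finite(curve$kleaf), ]
  if (nrow(curve) < 3) stop_invalid("need at least 3 vulnerability points")
  if (sd(curve$psi) == 0) stop_invalid("psi values must not all be identical")
  fit <- lm(kleaf ~ psi, data = curve)
  b <- unname(coef(fit))
  if (sd(curve$kleaf) == 0) b[2] <- 0 # constant K: no decline, not fp noise
  sm <- suppressWarnings(summary(fit)) # exact fits are legitimate here
  r2 <- sm$r.squared
  pval <- sm$coefficients["psi", "Pr(>|t|)"]
  if (method == "sma") {
    r <- cor(curve$psi, curve$kleaf)
    slope <- sign(r) * sd(curve$kleaf) / sd(curve$psi)
    b <- c(mean(curve$kleaf) - slope * mean(curve$psi), slope)
  }
  declines <- is.finite(b[2]) && b[2] > 0
  structure(list(
    K_max = b[1], slope = b[2],
    P50 = if (declines) -b[1] / (2 * b[2]) else NA_real_,
    r_squared = r2, p_value = pval, n = nrow(curve),
    method = method, declines = declines),
    class = "vulnerability_fit")
}

#' Fit vulnerability curves for many species
#'
#' @param curves `data.frame` with columns `species`, `psi`, `kleaf`.
#' @inheritParams fit_vulnerability
#' @return `data.frame` with one row per species: `K_max`, `slope`, `P50`,
#'   `r_squared`, `p_value`, `n`.
#' @export
fit_vulnerability_table <- function(curves, method = "ols") {
  rows <- lapply(split(curves, curves$species), function(d) {
    f <- fit_vulnerability(d[, c("psi", "kleaf")], method = method)
    data.frame(species = d$species[1], K_max = f$K_max, slope = f$slope,
               P50 = f$P50, r_squared = f$r_squared, p_value = f$p_value,
               n = f$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Add hydraulic supply/demand ratio columns to a trait table
#'
#' Row-wise ratios in the units conventional for each: `kleaf_gs` =
#' K_leaf / g_s (mmol mol^-1 MPa^-1 since K_leaf is in mmol and g_s in mol),
#' `wue_i` = A_area / g_s (umol mol^-1), `kleaf_aarea` = K_leaf / A_area.
#' Rows with non-positive divisors are flagged in `ratio_flag` and get `NA`
#' ratios.
#'
#' @param traits `data.frame` with (any of) columns `kleaf`
#'   (mmol m^-2 s^-1 MPa^-1), `gs` (mol m^-2 s^-1), `aarea`
#'   (umol m^-2 s^-1).
#' @return The table with ratio columns appended.
#' @export
trait_ratios <- function(traits) {
  stopifnot(is.data.frame(traits))
  flag <- rep(FALSE, nrow(traits))
  safe_div <- function(num, den) {
    bad <- !is.finite(den) | den <= 0
    flag <<- flag | (bad & !is.na(num))
    ifelse(bad, NA_real_, num / den)
  }
  if (all(c("kleaf", "gs") %in% names(traits))) {
    traits$kleaf_gs <- safe_div(traits$kleaf, traits$gs)
  }
  if (all(c("aarea", "gs") %in% names(traits))) {
    traits$wue_i <- safe_div(traits$aarea, traits$gs)
  }
  if (all(c("kleaf", "aarea") %in% names(traits))) {
    traits$kleaf_aarea <- safe_div(traits$kleaf, traits$aarea)
  }
  traits$ratio_flag <- flag
  traits
}

#' Aggregate per-study trait records to species means
#'
#' Meta-analysis aggregation: records from multiple studies are averaged per
#' species and trait with equal weight per record. The K_leaf:g_s ratio is
#' computed from the aggregated species means, but only for species for which
#' at least one study reported both K_leaf and g_s (ratio availability at the
#' species level cannot be manufactured from disjoint studies).
#'
#' @param records Long `data.frame` with columns `species`, `study`,
#'   `pathway`, `trait`, `value`.
#' @return Wide `data.frame`, one row per species with trait-mean columns
#'   plus `kleaf_gs` where defined.
#' @export
aggregate_species_means <- function(records) {
  need <- c("species", "study", "pathway", "trait", "value")
  if (!all(need %in% names(records))) {
    stop_schema("records need columns: ", paste(need, collapse = ", "))
  }
  pw <- unique(records[, c("species", "pathway")])
  if (anyDuplicated(pw$species)) {
    dup <- pw$species[duplicated(pw$species)]
    stop(errorCondition(
      paste0("conflicting pathway labels for: ", paste(dup, collapse = ", ")),
      class = c("grasshydro_consistency_error", "grasshydro_error")))
  }
  agg <- aggregate(value ~ species + trait, data = records, FUN = mean)
  wide <- stats::reshape(agg, idvar = "species", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  out <- merge(pw, wide, by = "species", sort = TRUE)
  # ratio only where some single study carried both traits for the species
  if (all(c("kleaf", "gs") %in% names(out))) {
    has_both <- vapply(out$species, function(sp) {
      d <- records[records$species == sp, ]
      any(vapply(split(d, d$study), function(s)
        all(c("kleaf", "gs") %in% s$trait), logical(1)))
    }, logical(1))
    out$kleaf_gs <- ifelse(has_both, out$kleaf / out$gs, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Pathway contrasts as percentages of the C3 mean
#'
#' For each trait column, the C3 and C4 means over species (each species
#' weighted once) and the C4 mean expressed as a percentage of the C3 mean
#' (100% = no contrast; e.g. 29% for a g_s that is 71% lower in C4).
#'
#' @param traits `data.frame` with a `pathway` column (`"C3"`/`"C4"`) and
#'   numeric trait columns.
#' @param trait_cols Columns to contrast; defaults to all numeric columns.
#' @param mean_type `"arithmetic"` (default, matching ANOVA-on-means
#'   framing) or `"geometric"`.
#' @return `data.frame` with columns `trait`, `c3_mean`, `c4_mean`,
#'   `pct_of_c3`.
#' @export
pathway_fold_differences <- function(traits, trait_cols = NULL,
                                     mean_type = c("arithmetic",
                                                   "geometric")) {
  mean_type <- match.arg(mean_type)
  if (!"pathway" %in% names(traits)) stop_schema("need a pathway column")
  if (!all(c("C3", "C4") %in% traits$pathway)) {
    stop(errorCondition("both pathways must be present for a contrast",
                        class = c("grasshydro_contrast_undefined",
                                  "grasshydro_error")))
  }
  if (is.null(trait_cols)) {
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  m <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    if (mean_type == "geometric") exp(mean(log(x))) else mean(x)
  }
  rows <- lapply(trait_cols, function(tr) {
    c3 <- m(traits[[tr]][traits$pathway == "C3"])
    c4 <- m(traits[[tr]][traits$pathway == "C4"])
    data.frame(trait = tr, c3_mean = c3, c4_mean = c4,
               pct_of_c3 = 100 * c4 / c3)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Two-sided critical values for Dixon's r10 (Q) statistic, alpha = 0.05 and
# 0.01, n = 3..30 (Rorabacher 1991 re-tabulation of Dixon's ratios).
DIXON_Q_CRIT <- list(
  "0.05" = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466, 0.444,
             0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356, 0.349, 0.342,
             0.337, 0.331, 0.326, 0.321, 0.317, 0.312, 0.308, 0.305, 0.301,
             0.298),
  "0.01" = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568, 0.542,
             0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442, 0.433, 0.425,
             0.418, 0.411, 0.404, 0.399, 0.393, 0.388, 0.384, 0.380, 0.376,
             0.372))

#' Dixon's Q test for a single outlier
#'
#' The Q10 variant: Q = (gap between the extreme value and its nearest
#' neighbour) / (range), evaluated at both ends and compared against the
#' published two-sided critical value. Valid for 3 <= n <= 30.
#'
#' @param values Numeric vector.
#' @param alpha Significance level, 0.05 or 0.01.
#' @return List with `Q` (the larger of the two end ratios), `critical`,
#'   `outlier_index` (index into `values`, or `NA` when nothing is flagged),
#'   `outlier_value`, `flagged`.
#' @examples
#' dixon_outlier_test(c(1.0, 1.1, 1.2, 5.0))$Q # 0.95
#' @export
dixon_outlier_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 30) stop_invalid("Dixon's test requires 3 <= n <= 30")
  key <- format(alpha, nsmall = 2)
  if (!key %in% names(DIXON_Q_CRIT)) {
    stop_invalid("critical values embedded for alpha = 0.05 and 0.01 only")
  }
  s <- sort(values)
  rng <- s[n] - s[1]
  if (rng == 0) {
    stop(errorCondition("zero range: Dixon's Q undefined",
                        class = c("grasshydro_degenerate_data",
                                  "grasshydro_error")))
  }
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    Q <- q_high; extreme <- s[n]
  } else {
    Q <- q_low; extreme <- s[1]
  }
  crit <- DIXON_Q_CRIT[[key]][n - 2]
  flagged <- Q > crit
  list(Q = Q, critical = crit,
       outlier_index = if (flagged) which(values == extreme)[1] else NA_integer_,
       outlier_value = if (flagged) extreme else NA_real_,
       flagged = flagged)
}

#' Hydraulic partition profile for a trait table
#'
#' Joins a trait table (K_leaf) with an anatomy hydraulics table (K_xc) and
#' computes K_oxc per species; species with infeasible partitions
#' (K_xc <= K_leaf) get `NA` and a flag rather than an error.
#'
#' @param traits `data.frame` with `species` and `kleaf` columns.
#' @param hydraulics `data.frame` with `species` and `K_xc` columns (e.g.
#'   from [anatomy_hydraulics_table()]).
#' @return Merged `data.frame` with `K_oxc` and `partition_ok` columns.
#' @export
partition_profile <- function(traits, hydraulics) {
  out <- merge(traits, hydraulics[, c("species", "K_xc")], by = "species")
  ok <- is.finite(out$kleaf) & is.finite(out$K_xc) & out$K_xc > out$kleaf &
    out$kleaf > 0
  out$K_oxc <- NA_real_
  out$K_oxc[ok] <- outside_xylem_conductance(out$kleaf[ok], out$K_xc[ok])
  out$partition_ok <- ok
  out
}
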