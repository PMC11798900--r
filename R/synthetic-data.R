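# Synthetic data with the statistical structure the analysis assumes: a
# pure-birth ultrametric tree, C4 photosynthesis arising on several
# independent branches, pathway-contrasted lognormal traits evolved with a
# Brownian component, per-vein-order conduit anatomy, and noisy linear
# vulnerability curves. The generator exists so every downstream stage is
# testable offline; it does not mimic any particular measured species set.

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the pathway contrasts the analysis is designed to detect:
#' C4 species with 71% lower stomatal conductance (fold 0.29), equal K_leaf,
#' 1.6-fold higher A_area and 1.8-fold higher vein density than C3 species.
#' Fold effects apply to the primitive traits only; contrasts in derived
#' ratios (e.g. K_leaf:g_s) follow from the primitive folds.
#'
#' @param n_species Number of tips.
#' @param n_c4_origins Number of independent C4 clades to place.
#' @param birth_rate Pure-birth speciation rate.
#' @param trait_means_c3 Named vector of C3 trait means in conventional
#'   units: `gs` (mol m^-2 s^-1), `kleaf` (mmol m^-2 s^-1 MPa^-1), `aarea`
#'   (umol m^-2 s^-1), `dv` (mm mm^-2).
#' @param pathway_fold_effects Named vector of multiplicative C4 effects;
#'   names must be a subset of `trait_means_c3`; all > 0.
#' @param bm_sigma Brownian rate on log scale (shared-ancestry deviations).
#' @param lognormal_cv Coefficient of variation of the multiplicative
#'   species-level noise (traits are positive and ratio-scaled, so noise is
#'   lognormal with unit mean).
#' @param seed RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 27, n_c4_origins = 11,
                             birth_rate = 1,
                             trait_means_c3 = c(gs = 0.30, kleaf = 8,
                                                aarea = 18, dv = 5),
                             pathway_fold_effects = c(gs = 0.29, kleaf = 1,
                                                      aarea = 1.6, dv = 1.8),
                             bm_sigma = 0.15, lognormal_cv = 0.2,
                             seed = 42) {
  if (n_species < 1) stop_invalid("n_species must be >= 1")
  if (n_c4_origins < 0 || n_c4_origins > n_species) {
    stop_invalid("n_c4_origins must be in [0, n_species]")
  }
  check_positive(birth_rate, "birth_rate")
  if (any(pathway_fold_effects <= 0)) stop_invalid("fold effects must be > 0")
  unknown <- setdiff(names(pathway_fold_effects), names(trait_means_c3))
  if (length(unknown)) {
    stop_invalid("fold effect for unknown trait: ",
                 paste(unknown, collapse = ", "))
  }
  if (bm_sigma < 0 || lognormal_cv < 0) {
    stop_invalid("bm_sigma and lognormal_cv must be >= 0")
  }
  structure(list(n_species = n_species, n_c4_origins = n_c4_origins,
                 birth_rate = birth_rate, trait_means_c3 = trait_means_c3,
                 pathway_fold_effects = pathway_fold_effects,
                 bm_sigma = bm_sigma, lognormal_cv = lognormal_cv,
                 seed = seed), class = "synthetic_config")
}

#' Simulate a pure-birth ultrametric tree
#'
#' @param n_species Number of tips (>= 1).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional RNG seed.
#' @return An ultrametric, binary, rooted `ape::phylo` tree with tip labels
#'   `s01, s02, ...`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (length(n_species) != 1 || n_species < 1 || n_species %% 1 != 0) {
    stop_invalid("n_species must be a positive integer")
  }
  check_positive(birth_rate, "birth_rate")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("s%02d", seq_len(n_species))
  if (n_species == 1) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         edge.length = rexp(1, birth_rate),
                         tip.label = labels[1], Nnode = 1L),
                    class = "phylo")
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tr$tip.label <- labels
  tr
}

# TRUE/FALSE per node (tips first), whether the whole clade below is C4
all_c4_below <- function(tree, is_c4_tip) {
  ntip <- length(tree$tip.label)
  all_c4 <- c(is_c4_tip, rep(TRUE, tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]; child <- eo$edge[i, 2]
    all_c4[par] <- all_c4[par] && all_c4[child]
  }
  all_c4
}

#' Count maximal monophyletic C4 clades
#'
#' A maximal C4 clade is a node (possibly a tip) whose descendant tips are
#' all C4 while its parent's are not. The count equals the number of
#' independent C4 origins implied by the labelling under parsimony without
#' reversals.
#'
#' @param tree An `ape::phylo` tree.
#' @param pathways Character vector of `"C3"`/`"C4"`, named by tip or in tip
#'   order.
#' @return Integer count of maximal C4 clades.
#' @export
count_c4_clades <- function(tree, pathways) {
  if (!is.null(names(pathways))) {
    pathways <- pathways[match(tree$tip.label, names(pathways))]
  }
  is_c4 <- pathways == "C4"
  if (!any(is_c4)) return(0L)
  ntip <- length(tree$tip.label)
  all_c4 <- all_c4_below(tree, is_c4)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  sum(vapply(seq_along(all_c4), function(nd) {
    all_c4[nd] && (nd == root || !all_c4[parent[nd]])
  }, logical(1)))
}

#' Place independent C4 origins on a tree
#'
#' Samples edges without replacement and labels the descendant tips of each
#' selected edge C4, discarding candidates that are nested in, contain, or
#' would merge with an already-selected clade. Selection is retried until
#' the labelling yields exactly `n_c4_origins` maximal C4 clades or the try
#' budget is exhausted, in which case the labelling closest to the request
#' is returned (the achieved count is always recoverable with
#' [count_c4_clades()]).
#'
#' @param tree An `ape::phylo` tree.
#' @param n_c4_origins Number of independent origins requested.
#' @param seed Optional RNG seed.
#' @param max_tries Resampling budget.
#' @return Character vector `"C3"`/`"C4"` named by tip label.
#' @export
assign_pathways <- function(tree, n_c4_origins, seed = NULL,
                            max_tries = 200) {
  ntip <- length(tree$tip.label)
  if (n_c4_origins > ntip) {
    stop_invalid("n_c4_origins cannot exceed the number of tips")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- setNames(rep("C3", ntip), tree$tip.label)
  if (n_c4_origins == 0) return(out)
  if (ntip == 1) {
    out[] <- "C4"
    return(out)
  }
  clade_tips <- tips_per_node(tree)
  # candidate clades: every edge's child (proper subsets of the tip set)
  cand <- lapply(tree$edge[, 2], function(nd) clade_tips[[nd]])
  best <- NULL
  best_gap <- Inf
  for (try in seq_len(max_tries)) {
    sel <- list()
    covered <- logical(ntip)
    for (j in sample(seq_along(cand))) {
      tp <- cand[[j]]
      if (any(covered[tp])) next
      if (sum(covered) + length(tp) >= ntip && n_c4_origins > 1) next
      covered[tp] <- TRUE
      sel <- c(sel, list(tp))
      if (length(sel) == n_c4_origins) break
    }
    lab <- out
    lab[unlist(sel)] <- "C4"
    achieved <- count_c4_clades(tree, lab)
    gap <- abs(achieved - n_c4_origins)
    if (gap < best_gap) {
      best <- lab
      best_gap <- gap
    }
    if (gap == 0) break
  }
  best
}

tips_per_node <- function(tree) {
  ntip <- length(tree$tip.label)
  tips <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) tips[[t]] <- t
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]; child <- eo$edge[i, 2]
    tips[[par]] <- c(tips[[par]], tips[[child]])
  }
  tips
}

#' Simulate pathway-contrasted traits on a tree
#'
#' Each trait is (C3 mean) x (fold effect if C4) x exp(Brownian deviation)
#' x lognormal noise with unit mean. With `bm_sigma = 0` and
#' `lognormal_cv = 0` every species takes its pathway mean exactly, so
#' configured contrasts round-trip exactly through the contrast statistics.
#' Derived ratio columns (`kleaf_gs`, `wue_i`, `kleaf_aarea`) are appended.
#'
#' @param tree An `ape::phylo` tree.
#' @param pathways `"C3"`/`"C4"` labels named by tip (from
#'   [assign_pathways()]).
#' @param config A [synthetic_config()]; its `seed` is used unless `seed`
#'   is given.
#' @param seed Optional RNG seed overriding the config's.
#' @return `data.frame` with `species`, `pathway`, the trait columns and
#'   derived ratios.
#' @export
simulate_traits <- function(tree, pathways, config = synthetic_config(),
                            seed = NULL) {
  if (!all(tree$tip.label %in% names(pathways))) {
    stop_invalid("pathway labels must cover all tips")
  }
  pathways <- pathways[match(tree$tip.label, names(pathways))]
  set.seed(seed %||% config$seed)
  n <- length(tree$tip.label)
  means <- config$trait_means_c3
  folds <- config$pathway_fold_effects
  sdlog <- sqrt(log(1 + config$lognormal_cv^2))
  out <- data.frame(species = tree$tip.label, pathway = unname(pathways))
  for (tr in names(means)) {
    fold <- if (tr %in% names(folds)) folds[[tr]] else 1
    base <- means[[tr]] * ifelse(pathways == "C4", fold, 1)
    bm <- if (config$bm_sigma > 0) {
      drop(simulate_bm(tree, sigma = config$bm_sigma, n = 1))
    } else rep(0, n)
    noise <- if (config$lognormal_cv > 0) {
      exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
    } else rep(1, n)
    out[[tr]] <- unname(base * exp(bm) * noise)
  }
  trait_ratios(out)
}

# Template conduit geometries (um) per vein order; jittered per species.
anatomy_template <- function(pathway, n_orders) {
  majors <- list(
    `1` = data.frame(
      type = c("protoxylem_lacuna", "xylem_I", "xylem_II"),
      major_axis_um = c(40, 30, 12), minor_axis_um = c(40, 24, 9),
      count = c(1, 2, 8)),
    `2` = data.frame(
      type = c("protoxylem_lacuna", "xylem_I", "xylem_II"),
      major_axis_um = c(28, 22, 10), minor_axis_um = c(28, 17, 8),
      count = c(1, 2, 6)),
    `3` = data.frame(type = "xylem_II", major_axis_um = 7,
                     minor_axis_um = 5, count = 4),
    `4` = data.frame(type = "xylem_II", major_axis_um = 5,
                     minor_axis_um = 4, count = 3))
  dv <- c(`1` = 0.08, `2` = 0.35, `3` = 4.5, `4` = 5.5)
  if (pathway == "C4") dv[c("3", "4")] <- dv[c("3", "4")] * 1.8
  bs_diam <- if (pathway == "C4") c(20, 18, 16, NA) else c(15, 13, 11, NA)
  bs_count <- c(14, 12, 10, 0)
  ms_diam <- c(8, 7, 6, 6)
  ms_count <- c(12, 10, 8, 6)
  list(conduits = majors, dv = dv, bs_diam = bs_diam, bs_count = bs_count,
       ms_diam = ms_diam, ms_count = ms_count)
}

#' Generate a synthetic leaf anatomy record
#'
#' Template geometries for a grass leaf of the given pathway with three (or,
#' for C4 only, four) longitudinal vein orders: protoxylem lacuna plus type
#' I and II conduits in the major orders, type II only in the minor orders,
#' vein density increasing toward the minor orders (higher for C4, echoing
#' Kranz anatomy), bundle and mestome sheath geometry, and leaf length.
#' A small multiplicative jitter (5% CV) individualises species.
#'
#' @param pathway `"C3"` or `"C4"`.
#' @param n_orders 3, or 4 (C4 only).
#' @param seed Optional RNG seed.
#' @param species Species id stored in the record.
#' @return A [leaf_anatomy()] record.
#' @export
generate_anatomy <- function(pathway = c("C3", "C4"), n_orders = 3,
                             seed = NULL, species = "synthetic") {
  pathway <- match.arg(pathway)
  if (!n_orders %in% c(3, 4)) stop_invalid("n_orders must be 3 or 4")
  if (n_orders == 4 && pathway == "C3") {
    stop_invalid("a fourth vein order occurs in C4 leaves only")
  }
  if (!is.null(seed)) set.seed(seed)
  tpl <- anatomy_template(pathway, n_orders)
  jit <- function(x) x * exp(rnorm(length(x), 0, 0.05))
  # jittered densities, re-sorted so Dv always increases toward the minor
  # orders (a structural invariant of the parallel grass vein hierarchy)
  dv_orders <- sort(jit(unname(tpl$dv[seq_len(n_orders)])))
  orders <- lapply(seq_len(n_orders), function(o) {
    cd <- tpl$conduits[[as.character(o)]]
    cd$major_axis_um <- jit(cd$major_axis_um)
    cd$minor_axis_um <- pmin(jit(cd$minor_axis_um), cd$major_axis_um)
    vein_order_anatomy(o, cd, dv = dv_orders[o],
                       bs_diam = if (is.na(tpl$bs_diam[o])) NA_real_
                                 else jit(tpl$bs_diam[o]),
                       bs_count = tpl$bs_count[o],
                       ms_diam = jit(tpl$ms_diam[o]),
                       ms_count = tpl$ms_count[o])
  })
  leaf_anatomy(species, pathway, orders,
               leaf_length = 0.35 * exp(rnorm(1, 0, 0.05)))
}

#' Generate a noisy linear vulnerability curve
#'
#' K = K_max + slope * Psi + Gaussian noise, truncated at zero, on an even
#' Psi grid over `psi_range` (default 0 to -2.5 MPa).
#'
#' @param K_max Conductance at Psi = 0 (> 0).
#' @param slope Decline per MPa (> 0, stored positive).
#' @param noise_sd Gaussian noise SD on K.
#' @param n_points Number of points (>= 3).
#' @param seed Optional RNG seed.
#' @param psi_range Length-2 range of Psi (MPa).
#' @return `data.frame` with `psi`, `kleaf`.
#' @export
generate_vulnerability_curve <- function(K_max, slope, noise_sd = 0,
                                         n_points = 10, seed = NULL,
                                         psi_range = c(-2.5, 0)) {
  check_positive(K_max, "K_max")
  check_positive(slope, "slope")
  if (n_points < 3) stop_invalid("n_points must be >= 3")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  psi <- seq(max(psi_range), min(psi_range), length.out = n_points)
  k <- K_max + slope * psi + rnorm(n_points, 0, noise_sd)
  data.frame(psi = psi, kleaf = pmax(k, 0))
}

#' Generate a complete synthetic dataset
#'
#' Tree, pathway labels, trait table, per-species anatomy and per-species
#' vulnerability curves, all driven by one config and seed. Optionally
#' writes the four standard files (newick tree, traits CSV, long-format
#' anatomy CSV, vulnerability CSV) to a directory.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return List with `tree`, `pathways`, `traits`, `anatomy` (named list of
#'   [leaf_anatomy()]), `vulnerability` (`data.frame` with `species`, `psi`,
#'   `kleaf`), and `files` when written.
#' @export
generate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        seed = config$seed)
  pathways <- assign_pathways(tree, config$n_c4_origins,
                              seed = config$seed + 1)
  traits <- simulate_traits(tree, pathways, config, seed = config$seed + 2)
  anatomy <- lapply(seq_len(config$n_species), function(i) {
    pw <- unname(pathways[tree$tip.label[i]])
    n_orders <- if (pw == "C4" && i %% 2 == 0) 4 else 3
    generate_anatomy(pw, n_orders, seed = config$seed + 100 + i,
                     species = tree$tip.label[i])
  })
  names(anatomy) <- tree$tip.label
  vuln <- do.call(rbind, lapply(seq_len(config$n_species), function(i) {
    kmax <- traits$kleaf[i] * 1.25 # curve intercept sits above the mean
    cv <- generate_vulnerability_curve(
      K_max = kmax, slope = kmax / 3.6, noise_sd = 0.05 * kmax,
      n_points = 10, seed = config$seed + 200 + i)
    cbind(species = tree$tip.label[i], cv)
  }))
  out <- list(tree = tree, pathways = pathways, traits = traits,
              anatomy = anatomy, vulnerability = vuln)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(tree = file.path(out_dir, "tree.nwk"),
               traits = file.path(out_dir, "traits.csv"),
               anatomy = file.path(out_dir, "anatomy.csv"),
               vulnerability = file.path(out_dir, "vulnerability.csv"))
    ape::write.tree(tree, files["tree"])
    meta <- c(seed = as.character(config$seed))
    write_csv_meta(traits, files["traits"], meta)
    write_anatomy_csv(anatomy, files["anatomy"], meta)
    write_csv_meta(vuln, files["vulnerability"], meta)
    out$files <- files
  }
  out
}
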