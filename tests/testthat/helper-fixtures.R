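# Fixtures built in code; frozen expected values were computed with an
# independent step-by-step arithmetic (SI units, conversion applied last)
# before the implementation was written against them.

# Fully specified 3-order leaf: protoxylem lacuna + type I + type II in the
# major orders, type II only in order 3.
fixture_leaf <- function() {
  o1 <- vein_order_anatomy(1, data.frame(
    type = c("protoxylem_lacuna", "xylem_I", "xylem_II"),
    major_axis_um = c(40, 30, 12), minor_axis_um = c(40, 24, 9),
    count = c(1, 2, 8)), dv = 0.08,
    bs_diam = 15, bs_count = 12, ms_diam = 8, ms_count = 10)
  o2 <- vein_order_anatomy(2, data.frame(
    type = c("protoxylem_lacuna", "xylem_I", "xylem_II"),
    major_axis_um = c(28, 22, 10), minor_axis_um = c(28, 17, 8),
    count = c(1, 2, 6)), dv = 0.35,
    bs_diam = 13, bs_count = 10, ms_diam = 7, ms_count = 9)
  o3 <- vein_order_anatomy(3, data.frame(
    type = "xylem_II", major_axis_um = 7, minor_axis_um = 5, count = 4),
    dv = 4.5, bs_diam = 11, bs_count = 8, ms_diam = 6, ms_count = 8)
  leaf_anatomy("fixture", "C3", list(o1, o2, o3), leaf_length = 0.35)
}

# frozen oracle values for the fixture (independent arithmetic)
FIXTURE_KXC <- 22.43394139783164
FIXTURE_MAJOR_FRACTION <- 0.96724202668998
ORACLE_KT_20_10 <- 4.903002467231708e-05
ORACLE_ORDER2_COMPOSITE <- 0.00151600149866459
ORACLE_C3_A_CI250 <- 11.948805243222111

# noise-free generator config used by the exact round-trip tests
exact_config <- function(n_species = 40, n_c4_origins = 8,
                         folds = c(gs = 0.5, kleaf = 1, aarea = 1.6,
                                   dv = 1.8),
                         seed = 42) {
  synthetic_config(n_species = n_species, n_c4_origins = n_c4_origins,
                   pathway_fold_effects = folds, bm_sigma = 0,
                   lognormal_cv = 0, seed = seed)
}

# independent maximal-clade counter built on ape primitives only: a node is
# a maximal C4 clade root if all its descendant tips are C4 and it is the
# root or its parent subtends at least one C3 tip
oracle_count_clades <- function(tree, pathways) {
  pw <- pathways[match(tree$tip.label, names(pathways))]
  ntip <- length(tree$tip.label)
  tips_of <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_of))
  }
  nodes <- seq_len(ntip + tree$Nnode)
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  count <- 0L
  for (nd in nodes) {
    tps <- tips_of(nd)
    if (!all(pw[tps] == "C4")) next
    par <- parent_of(nd)
    if (length(par) == 0 || !all(pw[tips_of(par)] == "C4")) {
      count <- count + 1L
    }
  }
  count
}
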