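# Vein xylem and sheath anatomy: theoretical conductance, construction cost,
# and sheath surface metrics for grass leaves with up to four parallel
# longitudinal vein orders.

CONDUIT_TYPES <- c("xylem_I", "xylem_II", "protoxylem_lacuna")

#' Construct a per-vein-order anatomy record
#'
#' A vein order record holds the measured conduits of that order (with
#' multiplicities), the order's vein density, and the bundle/mestome sheath
#' geometry. Major orders (1 and 2) may contain wide type I conduits, narrow
#' type II conduits and a single protoxylem lacuna; minor orders (3 and 4)
#' contain type II conduits only, as in grass leaves where protoxylem lacunae
#' and wide metaxylem are restricted to the major veins.
#'
#' @param order Vein order, one of 1, 2, 3, 4.
#' @param conduits `data.frame` with columns `type` (one of `"xylem_I"`,
#'   `"xylem_II"`, `"protoxylem_lacuna"`), `major_axis_um`, `minor_axis_um`
#'   (full ellipse axes, micrometres) and `count` (multiplicity).
#' @param dv Vein density of the order, mm of vein per mm^2 of leaf area.
#' @param bs_diam,bs_count Mean bundle sheath cell diameter (um) and number of
#'   bundle sheath cells around a vein of this order; `NA` when the order
#'   lacks a bundle sheath.
#' @param ms_diam,ms_count Same for the mestome sheath.
#' @return An object of class `vein_order_anatomy`.
#' @export
vein_order_anatomy <- function(order, conduits, dv,
                               bs_diam = NA_real_, bs_count = NA_real_,
                               ms_diam = NA_real_, ms_count = NA_real_) {
  if (!order %in% 1:4) stop_invalid("vein order must be 1, 2, 3 or 4")
  check_positive(dv, "dv")
  stopifnot(is.data.frame(conduits))
  need <- c("type", "major_axis_um", "minor_axis_um", "count")
  if (!all(need %in% names(conduits))) {
    stop_schema("conduit table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(conduits$type %in% CONDUIT_TYPES)) {
    stop_schema("unknown conduit type: ",
                paste(setdiff(conduits$type, CONDUIT_TYPES), collapse = ", "))
  }
  if (order >= 3 && any(conduits$type != "xylem_II")) {
    stop_schema("vein order ", order, " may contain xylem_II conduits only")
  }
  if (sum(conduits$count[conduits$type == "protoxylem_lacuna"]) > 1) {
    stop_schema("at most one protoxylem lacuna per vein order")
  }
  check_positive(conduits$major_axis_um, "major_axis_um")
  check_positive(conduits$minor_axis_um, "minor_axis_um")
  if (any(conduits$count < 0)) stop_invalid("conduit count must be >= 0")
  if (!is.na(bs_diam)) check_positive(bs_diam, "bs_diam")
  if (!is.na(ms_diam)) check_positive(ms_diam, "ms_diam")
  structure(list(order = as.integer(order), conduits = conduits, dv = dv,
                 bs_diam = bs_diam, bs_count = bs_count,
                 ms_diam = ms_diam, ms_count = ms_count),
            class = "vein_order_anatomy")
}

#' Construct a whole-leaf anatomy record
#'
#' @param species Species identifier.
#' @param pathway `"C3"` or `"C4"`.
#' @param orders List of [vein_order_anatomy()] records; the order set must be
#'   \{1,2,3\} or \{1,2,3,4\} (the fourth longitudinal order occurs only in
#'   some C4 Panicoideae).
#' @param leaf_length Leaf length, metres.
#' @param shape_correction Leaf shape area correction factor for linear
#'   leaves; dimensionless, in (0, 1]. Default 0.71.
#' @return An object of class `leaf_anatomy`.
#' @export
leaf_anatomy <- function(species, pathway, orders, leaf_length,
                         shape_correction = 0.71) {
  pathway <- match.arg(pathway, c("C3", "C4"))
  check_positive(leaf_length, "leaf_length")
  if (shape_correction <= 0 || shape_correction > 1) {
    stop_invalid("shape_correction must be in (0, 1]")
  }
  ords <- sort(unname(vapply(orders, function(o) o$order, integer(1))))
  if (!identical(ords, 1:3) && !identical(ords, 1:4)) {
    stop_schema("order set must be {1,2,3} or {1,2,3,4}, got {",
                paste(ords, collapse = ","), "}")
  }
  if (identical(ords, 1:4) && pathway == "C3") {
    stop_invalid("a fourth longitudinal vein order requires pathway C4")
  }
  orders <- orders[order(vapply(orders, function(o) o$order, integer(1)))]
  structure(list(species = species, pathway = pathway, orders = orders,
                 leaf_length = leaf_length,
                 shape_correction = shape_correction),
            class = "leaf_anatomy")
}

#' Theoretical conductivity of an elliptical xylem conduit
#'
#' Poiseuille's law modified for elliptical cross-sections:
#' k_t = (pi / (64 mu)) a^3 b^3 / (a^2 + b^2), with `a` and `b` the full
#' major and minor axes. For a circular conduit (a = b = 2r) this reduces
#' exactly to the classical Hagen-Poiseuille form pi r^4 / (8 mu). The
#' volumetric conductivity (m^4 MPa^-1 s^-1) is converted to molar units with
#' the molar density of liquid water.
#'
#' @param major_axis_um,minor_axis_um Full ellipse axes, micrometres
#'   (vectorised). Axes are canonicalised, so the result is symmetric in the
#'   two arguments.
#' @param constants A [hydro_constants()] object.
#' @return Conduit conductivity, mmol m s^-1 MPa^-1.
#' @examples
#' conduit_conductivity(20, 10)
#' @export
conduit_conductivity <- function(major_axis_um, minor_axis_um,
                                 constants = hydro_constants()) {
  check_positive(major_axis_um, "major_axis_um")
  check_positive(minor_axis_um, "minor_axis_um")
  a <- um_to_m(pmax(major_axis_um, minor_axis_um))
  b <- um_to_m(pmin(major_axis_um, minor_axis_um))
  vol <- pi / (64 * constants$water_viscosity) * a^3 * b^3 / (a^2 + b^2)
  vol * constants$molar_volume
}

#' Theoretical conductivity of one vein order
#'
#' Sums the conductivities of all conduits of all types present in the order
#' (type I and type II xylem plus the single protoxylem lacuna in the major
#' orders; type II only in the minor orders).
#'
#' @param vo A [vein_order_anatomy()] record.
#' @inheritParams conduit_conductivity
#' @return Order conductivity k_t, mmol m s^-1 MPa^-1.
#' @export
vein_order_conductivity <- function(vo, constants = hydro_constants()) {
  stopifnot(inherits(vo, "vein_order_anatomy"))
  cd <- vo$conduits
  if (nrow(cd) == 0) return(0)
  sum(conduit_conductivity(cd$major_axis_um, cd$minor_axis_um, constants) *
        cd$count)
}

#' Leaf-level theoretical xylem conductance from vein anatomy
#'
#' Computes whole-leaf conduit conductivity as the sum of per-order k_t, then
#' scales it to an area-normalised conductance by weighting each order's k_t
#' with its vein density, dividing by half the leaf length squared (so the
#' value represents the average axial pathway of a parallel vein system), and
#' dividing by the leaf shape area correction factor:
#'
#' K_xc = (sum_o k_t(o) Dv(o) / (0.5 LL^2)) / shape_correction
#'
#' The published denominator string is typographically ambiguous between
#' `0.5 * LL^2` and `(0.5 * LL)^2`; the former is the default and the latter
#' is available via `ll_convention = "half-then-square"`.
#'
#' @param leaf A [leaf_anatomy()] record.
#' @inheritParams conduit_conductivity
#' @param ll_convention How "half the leaf length squared" is parsed.
#' @return A list with `k_t_whole` (mmol m s^-1 MPa^-1), `K_xc`
#'   (mmol m^-2 s^-1 MPa^-1), per-order conductivities `k_t_order`, per-order
#'   contributions to K_xc, and `major_fraction`, the share of K_xc carried by
#'   vein orders 1 and 2.
#' @export
leaf_xylem_conductance <- function(leaf, constants = hydro_constants(),
                                   ll_convention = c("half-squared",
                                                     "half-then-square")) {
  stopifnot(inherits(leaf, "leaf_anatomy"))
  ll_convention <- match.arg(ll_convention)
  kt <- vapply(leaf$orders, vein_order_conductivity, numeric(1),
               constants = constants)
  ords <- vapply(leaf$orders, function(o) o$order, integer(1))
  names(kt) <- paste0("order", ords)
  dv <- vapply(leaf$orders, function(o) o$dv, numeric(1))
  if (any(!is.finite(dv))) stop_schema("missing Dv for a present vein order")
  denom <- switch(ll_convention,
                  "half-squared" = 0.5 * leaf$leaf_length^2,
                  "half-then-square" = (0.5 * leaf$leaf_length)^2)
  contrib <- kt * mm_per_mm2_to_per_m(dv) / denom / leaf$shape_correction
  names(contrib) <- names(kt)
  K_xc <- sum(contrib)
  major <- ords %in% c(1L, 2L)
  list(k_t_whole = sum(kt),
       K_xc = K_xc,
       k_t_order = kt,
       contribution = contrib,
       major_fraction = if (K_xc > 0) sum(contrib[major]) / K_xc else NA_real_)
}

#' Xylem construction cost index
#'
#' Index of xylem cell wall volume per leaf area for a vein order,
#' CC = pi CD^exponent CN Dv, assuming constant wall thickness at
#' `exponent = 1`. Setting `exponent < 1` accounts for wider conduits having
#' proportionally thinner walls.
#'
#' @param cd Mean conduit diameter of the order (um).
#' @param cn Conduit number of the order.
#' @param dv Vein density of the order (mm mm^-2).
#' @param exponent Exponent applied to `cd`; must be > 0, at most 1 makes
#'   physical sense.
#' @return Construction cost index (index units; inputs are not converted).
#' @examples
#' construction_cost(10, 3, 5) # pi * 150
#' @export
construction_cost <- function(cd, cn, dv, exponent = 1) {
  if (any(cd < 0) || any(cn < 0) || any(dv < 0)) {
    stop_invalid("cd, cn and dv must be >= 0")
  }
  if (exponent <= 0) stop_invalid("exponent must be > 0")
  pi * cd^exponent * cn * dv
}

sheath_fields <- function(leaf, tissue) {
  d <- vapply(leaf$orders, function(o) o[[paste0(tissue, "_diam")]],
              numeric(1))
  n <- vapply(leaf$orders, function(o) o[[paste0(tissue, "_count")]],
              numeric(1))
  ok <- !is.na(d) & !is.na(n) & n > 0
  list(d = d, n = n, ok = ok,
       orders = vapply(leaf$orders, function(o) o$order, integer(1)))
}

#' Mean outer sheath perimeter across vein orders
#'
#' For each vein order possessing the tissue, the outer perimeter is
#' approximated as half the circumference of a circle with the mean sheath
#' cell diameter, times the cell number: (D/2) pi N. The reported P_bs and
#' P_ms are means over the orders that possess that sheath (three orders for
#' the bundle sheath in the typical grass layout, up to four for the mestome
#' sheath).
#'
#' @param leaf A [leaf_anatomy()] record.
#' @return List with `P_bs` and `P_ms` (um), each `NA` with an
#'   `absent_tissue` condition if no order possesses that sheath.
#' @export
sheath_perimeter <- function(leaf) {
  stopifnot(inherits(leaf, "leaf_anatomy"))
  one <- function(tissue) {
    f <- sheath_fields(leaf, tissue)
    if (!any(f$ok)) {
      stop(errorCondition(
        paste0("no vein order possesses a ", tissue, " sheath"),
        class = c("grasshydro_absent_tissue", "grasshydro_error")))
    }
    mean((f$d[f$ok] / 2) * pi * f$n[f$ok])
  }
  list(P_bs = one("bs"), P_ms = one("ms"))
}

#' Sheath surface area, projected area and volume per leaf area
#'
#' Per vein order: surface area per leaf area SA = D pi Dv N, projected area
#' PA = D Dv N, and volume per leaf area V = (D/2)^2 pi Dv N, with D the mean
#' sheath cell diameter, N the cell count, and Dv the vein density of the
#' order. Orders 1-2 are reported as the major split, orders 3-4 as the minor
#' split. Diameters are converted from um to m and Dv from mm mm^-2 to m^-1,
#' so SA and PA are dimensionless (m^2 per m^2 leaf) and V is in m^3 m^-2.
#'
#' @param leaf A [leaf_anatomy()] record.
#' @return Named list with `BSSA`, `BSPA`, `BSV`, `MSSA`, `MSPA`, `MSV`, each
#'   a list with `total`, `major`, `minor`. Absent tissue raises an
#'   `absent_tissue` condition.
#' @export
sheath_area_volume <- function(leaf) {
  stopifnot(inherits(leaf, "leaf_anatomy"))
  dv <- vapply(leaf$orders, function(o) o$dv, numeric(1))
  ords <- vapply(leaf$orders, function(o) o$order, integer(1))
  one <- function(tissue) {
    f <- sheath_fields(leaf, tissue)
    if (!any(f$ok)) {
      stop(errorCondition(
        paste0("no vein order possesses a ", tissue, " sheath"),
        class = c("grasshydro_absent_tissue", "grasshydro_error")))
    }
    d <- um_to_m(f$d)
    dvm <- mm_per_mm2_to_per_m(dv)
    sa <- ifelse(f$ok, d * pi * dvm * f$n, 0)
    pa <- ifelse(f$ok, d * dvm * f$n, 0)
    vv <- ifelse(f$ok, (d / 2)^2 * pi * dvm * f$n, 0)
    major <- ords %in% c(1L, 2L)
    split <- function(x) list(total = sum(x), major = sum(x[major]),
                              minor = sum(x[!major]))
    list(SA = split(sa), PA = split(pa), V = split(vv))
  }
  bs <- one("bs")
  ms <- one("ms")
  list(BSSA = bs$SA, BSPA = bs$PA, BSV = bs$V,
       MSSA = ms$SA, MSPA = ms$PA, MSV = ms$V)
}

#' Validate a leaf anatomy record
#'
#' Returns a character vector of schema violations (empty when clean):
#' illegal conduit types for the order, non-positive dimensions or densities,
#' non-positive leaf length, illegal order sets.
#'
#' @param leaf A [leaf_anatomy()] record, or a long-format anatomy
#'   `data.frame` (see [read_anatomy_csv()]).
#' @return Character vector of violation messages.
#' @export
validate_leaf_anatomy <- function(leaf) {
  if (is.data.frame(leaf)) {
    return(unlist(lapply(split(leaf, leaf$species), validate_anatomy_df_one)))
  }
  stopifnot(inherits(leaf, "leaf_anatomy"))
  out <- character(0)
  for (o in leaf$orders) {
    if (o$order >= 3 && any(o$conduits$type != "xylem_II")) {
      out <- c(out, sprintf(
        "%s: order %d contains %s but minor orders carry xylem_II only",
        leaf$species, o$order,
        paste(setdiff(o$conduits$type, "xylem_II"), collapse = "/")))
    }
  }
  out
}

validate_anatomy_df_one <- function(df) {
  out <- character(0)
  sp <- df$species[1]
  bad <- df$vein_order >= 3 & df$conduit_type != "xylem_II"
  if (any(bad)) {
    out <- c(out, sprintf(
      "%s: row with %s in vein order %d (minor orders carry xylem_II only)",
      sp, df$conduit_type[bad], df$vein_order[bad]))
  }
  num <- c("major_axis_um", "minor_axis_um", "Dv_mm_mm2", "leaf_length_cm")
  for (v in num) {
    if (v %in% names(df) && any(!is.na(df[[v]]) & df[[v]] <= 0)) {
      out <- c(out, sprintf("%s: non-positive %s", sp, v))
    }
  }
  out
}

#' Read / write long-format anatomy tables
#'
#' One row per (species, vein order, conduit type). Order-level columns
#' (`Dv_mm_mm2`, sheath geometry, `leaf_length_cm`, `pathway`) are repeated
#' across the conduit rows of the order.
#'
#' @param path CSV file path.
#' @return `read_anatomy_csv`: a named list of [leaf_anatomy()] records.
#' @export
read_anatomy_csv <- function(path) {
  df <- read_csv_meta(path)
  anatomy_from_df(df)
}

#' @rdname read_anatomy_csv
#' @param leaves Named list of [leaf_anatomy()] records.
#' @param meta Optional named character vector written as a commented header.
#' @export
write_anatomy_csv <- function(leaves, path, meta = NULL) {
  df <- do.call(rbind, lapply(leaves, anatomy_to_df))
  rownames(df) <- NULL
  write_csv_meta(df, path, meta)
  invisible(path)
}

#' @rdname read_anatomy_csv
#' @param df Long-format anatomy `data.frame`.
#' @export
anatomy_from_df <- function(df) {
  need <- c("species", "pathway", "vein_order", "conduit_type",
            "major_axis_um", "minor_axis_um", "conduit_count", "Dv_mm_mm2",
            "leaf_length_cm")
  if (!all(need %in% names(df))) {
    stop_schema("anatomy table needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$species), function(d) {
    orders <- lapply(split(d, d$vein_order), function(o) {
      vein_order_anatomy(
        order = o$vein_order[1],
        conduits = data.frame(type = o$conduit_type,
                              major_axis_um = o$major_axis_um,
                              minor_axis_um = o$minor_axis_um,
                              count = o$conduit_count),
        dv = o$Dv_mm_mm2[1],
        bs_diam = (o$bs_cell_diam_um %||% NA_real_)[1],
        bs_count = (o$bs_cell_count %||% NA_real_)[1],
        ms_diam = (o$ms_cell_diam_um %||% NA_real_)[1],
        ms_count = (o$ms_cell_count %||% NA_real_)[1])
    })
    leaf_anatomy(d$species[1], d$pathway[1], orders,
                 leaf_length = d$leaf_length_cm[1] / 100)
  })
  out[unique(df$species)]
}

anatomy_to_df <- function(leaf) {
  do.call(rbind, lapply(leaf$orders, function(o) {
    data.frame(species = leaf$species, pathway = leaf$pathway,
               vein_order = o$order, conduit_type = o$conduits$type,
               major_axis_um = o$conduits$major_axis_um,
               minor_axis_um = o$conduits$minor_axis_um,
               conduit_count = o$conduits$count,
               Dv_mm_mm2 = o$dv,
               bs_cell_diam_um = o$bs_diam, bs_cell_count = o$bs_count,
               ms_cell_diam_um = o$ms_diam, ms_cell_count = o$ms_count,
               leaf_length_cm = leaf$leaf_length * 100)
  }))
}

#' Per-species anatomical hydraulics summary
#'
#' Runs the full anatomy pipeline for each species: per-order and whole-leaf
#' conductivity, K_xc and major-vein share, construction cost of major, minor
#' and all veins, sheath perimeters, and sheath area/volume metrics.
#'
#' @param leaves Named list of [leaf_anatomy()] records.
#' @inheritParams leaf_xylem_conductance
#' @param cc_exponent Exponent for [construction_cost()].
#' @return `data.frame`, one row per species.
#' @export
anatomy_hydraulics_table <- function(leaves, constants = hydro_constants(),
                                     ll_convention = "half-squared",
                                     cc_exponent = 1) {
  rows <- lapply(leaves, function(leaf) {
    kx <- leaf_xylem_conductance(leaf, constants, ll_convention)
    ords <- vapply(leaf$orders, function(o) o$order, integer(1))
    cc <- vapply(leaf$orders, function(o) {
      cd <- with(o$conduits, stats::weighted.mean(
        (major_axis_um + minor_axis_um) / 2, count))
      construction_cost(cd, sum(o$conduits$count), o$dv, cc_exponent)
    }, numeric(1))
    per <- tryCatch(sheath_perimeter(leaf),
                    grasshydro_absent_tissue = function(e)
                      list(P_bs = NA_real_, P_ms = NA_real_))
    sav <- tryCatch(sheath_area_volume(leaf),
                    grasshydro_absent_tissue = function(e) NULL)
    kt <- rep(NA_real_, 4)
    kt[ords] <- kx$k_t_order
    data.frame(
      species = leaf$species, pathway = leaf$pathway,
      k_t_order1 = kt[1], k_t_order2 = kt[2], k_t_order3 = kt[3],
      k_t_order4 = kt[4], k_t_whole = kx$k_t_whole, K_xc = kx$K_xc,
      major_fraction = kx$major_fraction,
      CC_major = sum(cc[ords <= 2]), CC_minor = sum(cc[ords >= 3]),
      CC_total = sum(cc),
      P_bs = per$P_bs, P_ms = per$P_ms,
      BSSA = if (is.null(sav)) NA_real_ else sav$BSSA$total,
      BSPA = if (is.null(sav)) NA_real_ else sav$BSPA$total,
      BSV = if (is.null(sav)) NA_real_ else sav$BSV$total,
      MSSA = if (is.null(sav)) NA_real_ else sav$MSSA$total,
      MSPA = if (is.null(sav)) NA_real_ else sav$MSPA$total,
      MSV = if (is.null(sav)) NA_real_ else sav$MSV$total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
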