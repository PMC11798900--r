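test_that("elliptical conductivity reduces to Hagen-Poiseuille for circles", {
  ct <- hydro_constants()
  for (r_um in c(2, 5, 14, 25)) {
    k_ell <- conduit_conductivity(2 * r_um, 2 * r_um, ct)
    r <- r_um * 1e-6
    k_hp <- pi * r^4 / (8 * ct$water_viscosity) * ct$molar_volume
    expect_lt(abs(k_ell - k_hp) / k_hp, 1e-12)
  }
})

test_that("conduit conductivity is symmetric in the axes and matches the
           frozen oracle", {
  expect_identical(conduit_conductivity(20, 10), conduit_conductivity(10, 20))
  expect_equal(conduit_conductivity(20, 10), ORACLE_KT_20_10,
               tolerance = 1e-12)
  expect_error(conduit_conductivity(-1, 5), class =
                 "grasshydro_invalid_parameter")
})

test_that("vein order conductivity is additive over conduits", {
  one <- vein_order_anatomy(3, data.frame(
    type = "xylem_II", major_axis_um = 8, minor_axis_um = 6, count = 1),
    dv = 4)
  expect_equal(vein_order_conductivity(one), conduit_conductivity(8, 6))
  two <- one
  two$conduits$count <- 2
  expect_equal(vein_order_conductivity(two),
               2 * vein_order_conductivity(one))
  # order 2 composite: lacuna + 2 type I + 3 type II, frozen compositional
  # oracle
  o2 <- vein_order_anatomy(2, data.frame(
    type = c("protoxylem_lacuna", "xylem_I", "xylem_II"),
    major_axis_um = c(30, 20, 8), minor_axis_um = c(30, 15, 6),
    count = c(1, 2, 3)), dv = 0.3)
  expect_equal(vein_order_conductivity(o2), ORACLE_ORDER2_COMPOSITE,
               tolerance = 1e-12)
})

test_that("minor vein orders reject type I conduits and lacunae", {
  expect_error(vein_order_anatomy(3, data.frame(
    type = "xylem_I", major_axis_um = 10, minor_axis_um = 8, count = 1),
    dv = 4), class = "grasshydro_schema_error")
  expect_error(vein_order_anatomy(4, data.frame(
    type = "protoxylem_lacuna", major_axis_um = 20, minor_axis_um = 20,
    count = 1), dv = 4), class = "grasshydro_schema_error")
})

test_that("leaf xylem conductance matches the end-to-end hand oracle and
           scales as expected", {
  leaf <- fixture_leaf()
  kx <- leaf_xylem_conductance(leaf)
  expect_lt(abs(kx$K_xc - FIXTURE_KXC) / FIXTURE_KXC, 1e-9)
  expect_equal(kx$major_fraction, FIXTURE_MAJOR_FRACTION, tolerance = 1e-9)

  # linear in Dv
  leaf2 <- leaf
  leaf2$orders <- lapply(leaf$orders, function(o) { o$dv <- 2 * o$dv; o })
  expect_equal(leaf_xylem_conductance(leaf2)$K_xc, 2 * kx$K_xc)

  # LL^-2 scaling
  leaf3 <- leaf
  leaf3$leaf_length <- 2 * leaf$leaf_length
  expect_equal(leaf_xylem_conductance(leaf3)$K_xc, kx$K_xc / 4)

  # alternative leaf-length convention: (0.5 LL)^2 halves the denominator
  kx_alt <- leaf_xylem_conductance(leaf, ll_convention = "half-then-square")
  expect_equal(kx_alt$K_xc, 2 * kx$K_xc)

  # order invariance: shuffling conduit rows changes nothing
  leaf4 <- leaf
  leaf4$orders[[1]]$conduits <- leaf$orders[[1]]$conduits[c(3, 1, 2), ]
  expect_equal(leaf_xylem_conductance(leaf4)$K_xc, kx$K_xc)
})

test_that("construction cost behaves as a monotone product index", {
  expect_equal(construction_cost(10, 0, 5), 0)
  expect_equal(construction_cost(10, 3, 5), pi * 150)
  expect_lt(construction_cost(10, 3, 5, exponent = 0.8),
            construction_cost(10, 3, 5, exponent = 1))
  expect_error(construction_cost(10, 3, 5, exponent = 0),
               class = "grasshydro_invalid_parameter")
})

test_that("sheath perimeter averages half-circumference over possessing
           orders", {
  leaf <- fixture_leaf()
  # single-order formula: (D/2) * pi * N
  one <- leaf
  one$orders[[2]]$bs_diam <- NA_real_
  one$orders[[3]]$bs_diam <- NA_real_
  one$orders[[1]]$bs_diam <- 10
  one$orders[[1]]$bs_count <- 1
  expect_equal(sheath_perimeter(one)$P_bs, 5 * pi)
  # identical orders: mean equals the per-order value
  same <- leaf
  for (i in 1:3) {
    same$orders[[i]]$bs_diam <- 12
    same$orders[[i]]$bs_count <- 8
  }
  expect_equal(sheath_perimeter(same)$P_bs, (12 / 2) * pi * 8)
  # frozen four-order arithmetic oracle (D = 12,10,8,6; N = 10,8,6,4)
  four <- generate_anatomy("C4", 4, seed = 1)
  d <- c(12, 10, 8, 6); n <- c(10, 8, 6, 4)
  for (i in 1:4) {
    four$orders[[i]]$ms_diam <- d[i]
    four$orders[[i]]$ms_count <- n[i]
  }
  expect_equal(sheath_perimeter(four)$P_ms, 106.81415022205294,
               tolerance = 1e-12)
})

test_that("sheath area and volume metrics keep their formula ratios and
           match the unit-conversion oracle", {
  leaf <- fixture_leaf()
  sav <- sheath_area_volume(leaf)
  expect_equal(sav$BSPA$total, sav$BSSA$total / pi)
  # per-order V = SA * D/4; verify on a single possessing order
  one <- leaf
  one$orders[[2]]$bs_diam <- NA_real_
  one$orders[[3]]$bs_diam <- NA_real_
  one$orders[[1]]$bs_diam <- 10
  one$orders[[1]]$bs_count <- 6
  one$orders[[1]]$dv <- 4
  s1 <- sheath_area_volume(one)
  expect_equal(s1$BSSA$total, 0.7539822368615504, tolerance = 1e-12)
  expect_equal(s1$BSPA$total, 0.24, tolerance = 1e-12)
  expect_equal(s1$BSV$total, 1.8849555921538758e-06, tolerance = 1e-12)
  expect_equal(s1$BSV$total, s1$BSSA$total * (10e-6) / 4)
})

test_that("absent sheath tissue is a distinct signal, not zero", {
  leaf <- fixture_leaf()
  for (i in 1:3) leaf$orders[[i]]$bs_diam <- NA_real_
  expect_error(sheath_perimeter(leaf), class = "grasshydro_absent_tissue")
  expect_error(sheath_area_volume(leaf), class = "grasshydro_absent_tissue")
})

test_that("anatomy tables round-trip through CSV and validate cleanly", {
  leaves <- list(a = generate_anatomy("C3", 3, seed = 1, species = "a"),
                 b = generate_anatomy("C4", 4, seed = 2, species = "b"))
  tmp <- tempfile(fileext = ".csv")
  write_anatomy_csv(leaves, tmp)
  back <- read_anatomy_csv(tmp)
  expect_named(back, c("a", "b"))
  expect_equal(leaf_xylem_conductance(back$a)$K_xc,
               leaf_xylem_conductance(leaves$a)$K_xc, tolerance = 1e-9)
  expect_length(validate_leaf_anatomy(back$a), 0)
  unlink(tmp)
})
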