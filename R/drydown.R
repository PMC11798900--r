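# Quasi-static soil dry-down simulator: at each step the leaf water
# potential is solved so hydraulic supply K_leaf(Psi_leaf) (Psi_soil -
# Psi_leaf) balances transpirational demand E = gs(Psi_leaf) VPD / Patm,
# assimilation follows from the stomatal CO2 coupling, and the soil bucket
# is depleted by the transpired water.

#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Saturation vapour pressure by the Tetens formula,
#' es(T) = 0.6108 exp(17.27 T / (T + 237.3)) kPa, and VPD = es (1 - RH).
#'
#' @param t_air Air temperature, degrees C, in [-10, 50].
#' @param rh Relative humidity as a fraction in [0, 1].
#' @return VPD, kPa.
#' @examples
#' vpd_from_climate(20, 0.786) # ~0.5 kPa
#' vpd_from_climate(30, 0.295) # ~3.0 kPa
#' @export
vpd_from_climate <- function(t_air, rh) {
  if (any(t_air < -10 | t_air > 50)) {
    stop_invalid("t_air must be in [-10, 50] C")
  }
  if (any(rh < 0 | rh > 1)) stop_invalid("rh must be in [0, 1]")
  es <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))
  es * (1 - rh)
}

#' Environment for a simulation
#'
#' @param t_air Air temperature, C.
#' @param rh Relative humidity fraction.
#' @param Ca Ambient CO2, umol mol^-1.
#' @param Patm Atmospheric pressure, kPa.
#' @return List of class `sim_environment` with derived `vpd` (kPa).
#' @export
sim_environment <- function(t_air = 20, rh = 0.786, Ca = 400, Patm = 101.3) {
  structure(list(t_air = t_air, rh = rh, vpd = vpd_from_climate(t_air, rh),
                 Ca = Ca, Patm = Patm), class = "sim_environment")
}

#' Plant scenario for the dry-down simulator
#'
#' Bundles the stomatal closure sigmoid, the linear hydraulic decline, and
#' the photosynthesis parameters of one simulated plant type.
#'
#' @param label Scenario name.
#' @param g_max Maximal stomatal conductance, mol m^-2 s^-1.
#' @param psi_gs50 Leaf water potential at 50% stomatal closure, MPa (< 0).
#' @param c Sigmoid steepness constant, MPa (> 0).
#' @param K_max Maximum leaf hydraulic conductance, mmol m^-2 s^-1 MPa^-1.
#' @param vuln_slope Slope of the linear K_leaf decline, mmol m^-2 s^-1
#'   MPa^-2, stored positive and applied to negative water potentials.
#' @param K_floor Residual conductance fraction of `K_max` in [0, 0.1]
#'   (keeps the supply function positive at extreme dehydration).
#' @param photo [c3_params()] or [c4_params()].
#' @param target_psi_leaf Optional operational leaf water potential at field
#'   capacity, MPa, used by [calibrate_conductance()].
#' @return List of class `plant_scenario`.
#' @export
plant_scenario <- function(label, g_max, psi_gs50, c, K_max, vuln_slope,
                           K_floor = 0.05, photo = c3_params(),
                           target_psi_leaf = NULL) {
  check_positive(g_max, "g_max")
  check_positive(K_max, "K_max")
  if (psi_gs50 >= 0) stop_invalid("psi_gs50 must be < 0")
  if (c <= 0) stop_invalid("sigmoid constant c must be > 0")
  if (vuln_slope < 0) stop_invalid("vuln_slope is stored positive")
  if (K_floor < 0 || K_floor > 0.1) stop_invalid("K_floor must be in [0, 0.1]")
  structure(list(label = label, g_max = g_max, psi_gs50 = psi_gs50, c = c,
                 K_max = K_max, vuln_slope = vuln_slope, K_floor = K_floor,
                 photo = photo, target_psi_leaf = target_psi_leaf),
            class = "plant_scenario")
}

#' Stomatal conductance response to leaf water potential
#'
#' gs = g_max / (1 + exp((psi_gs50 - psi_leaf) / c)). With c > 0 this is
#' non-increasing as the leaf dehydrates (psi_leaf more negative) and equals
#' g_max/2 at psi_gs50.
#'
#' @param psi_leaf Leaf water potential, MPa (vectorised, <= 0).
#' @param scenario A [plant_scenario()].
#' @return gs, mol m^-2 s^-1, in (0, g_max).
#' @export
stomatal_response <- function(psi_leaf, scenario) {
  if (any(psi_leaf > 0)) stop_invalid("psi_leaf must be <= 0")
  scenario$g_max / (1 + exp((scenario$psi_gs50 - psi_leaf) / scenario$c))
}

#' Leaf hydraulic conductance response to leaf water potential
#'
#' K_leaf = max(K_max + a psi_leaf, K_floor K_max): the linear vulnerability
#' decline, clamped at a small residual conductance.
#'
#' @inheritParams stomatal_response
#' @return K_leaf, mmol m^-2 s^-1 MPa^-1.
#' @export
kleaf_response <- function(psi_leaf, scenario) {
  if (any(psi_leaf > 0)) stop_invalid("psi_leaf must be <= 0")
  pmax(scenario$K_max + scenario$vuln_slope * psi_leaf,
       scenario$K_floor * scenario$K_max)
}

#' Soil water retention (Campbell power law)
#'
#' Psi_soil = Psi_e theta_rel^(-b): air-entry potential at saturation,
#' steeply more negative as the relative water content falls.
#'
#' @param theta_rel Relative soil water content in (0, 1] (vectorised).
#' @param psi_e Air-entry water potential, MPa (< 0).
#' @param b Retention exponent (> 0).
#' @return Psi_soil, MPa.
#' @export
soil_water_potential <- function(theta_rel, psi_e = -0.002, b = 6) {
  if (any(theta_rel <= 0 | theta_rel > 1)) {
    stop_invalid("theta_rel must be in (0, 1]")
  }
  if (psi_e >= 0) stop_invalid("psi_e must be < 0")
  check_positive(b, "b")
  psi_e * theta_rel^(-b)
}

#' Soil bucket state
#'
#' @param bucket_size Plant-available water per unit leaf area at
#'   saturation, mol m^-2.
#' @inheritParams soil_water_potential
#' @return List of class `soil_state`.
#' @export
soil_state <- function(bucket_size = 2500, psi_e = -0.002, b = 6,
                       theta_rel = 1) {
  check_positive(bucket_size, "bucket_size")
  structure(list(bucket_size = bucket_size, psi_e = psi_e, b = b,
                 theta_rel = theta_rel), class = "soil_state")
}

# supply - demand residual (mmol m^-2 s^-1) at a candidate psi_leaf
supply_demand_residual <- function(psi_leaf, psi_soil, env, scenario) {
  supply <- kleaf_response(psi_leaf, scenario) * (psi_soil - psi_leaf)
  demand <- stomatal_response(psi_leaf, scenario) * 1000 *
    env$vpd / env$Patm
  supply - demand
}

#' Solve the steady-state leaf water balance
#'
#' Finds the leaf water potential at which hydraulic supply through the leaf,
#' K_leaf(Psi_leaf) (Psi_soil - Psi_leaf), equals transpirational demand,
#' E = gs(Psi_leaf) VPD / Patm (converted to mmol m^-2 s^-1). When the
#' balance has multiple roots the wettest (highest Psi_leaf) stable state is
#' returned. Assimilation is computed from the solved gs via
#' [couple_diffusion()].
#'
#' @param psi_soil Soil water potential, MPa (<= air-entry).
#' @param env A [sim_environment()].
#' @param scenario A [plant_scenario()].
#' @param psi_min Lower search bound for Psi_leaf, MPa.
#' @param tol Supply-demand residual tolerance, mmol m^-2 s^-1.
#' @param n_grid Bracketing grid size.
#' @return List with `psi_leaf`, `gs`, `E` (mmol m^-2 s^-1), `A`, `Ci`,
#'   `kleaf`, `residual`, `desiccated`.
#' @export
solve_steady_state <- function(psi_soil, env, scenario, psi_min = -10,
                               tol = 1e-8, n_grid = 200) {
  if (psi_soil > 0) stop_invalid("psi_soil must be <= 0")
  f <- function(p) supply_demand_residual(p, psi_soil, env, scenario)
  if (env$vpd == 0) {
    return(steady_state_at(psi_soil, psi_soil, env, scenario))
  }
  # supply is zero at psi_soil (f < 0 there); march downward to the first
  # sign change, which brackets the wettest root
  grid <- seq(psi_soil, psi_min, length.out = n_grid)
  fv <- f(grid)
  idx <- which(fv >= 0)[1]
  if (is.na(idx)) {
    # no root above psi_min: desiccation, report the closed-stomata state
    out <- steady_state_at(psi_min, psi_soil, env, scenario)
    out$desiccated <- TRUE
    return(out)
  }
  if (idx == 1L) {
    root <- grid[1]
  } else {
    root <- uniroot(f, c(grid[idx], grid[idx - 1L]), tol = 1e-14)$root
    a <- grid[idx]; b <- grid[idx - 1L]
    for (i in 1:200) {
      if (abs(f(root)) < tol) break
      if (f(root) > 0) a <- root else b <- root
      root <- (a + b) / 2
    }
  }
  out <- steady_state_at(root, psi_soil, env, scenario)
  if (abs(out$residual) >= tol) {
    stop(errorCondition(
      sprintf("steady state did not converge (residual %.3e)", out$residual),
      class = c("grasshydro_numerical_error", "grasshydro_error")))
  }
  out
}

steady_state_at <- function(psi_leaf, psi_soil, env, scenario) {
  gs <- stomatal_response(psi_leaf, scenario)
  E <- gs * 1000 * env$vpd / env$Patm
  cp <- couple_diffusion(gs, air_state(Ca = env$Ca, Patm = env$Patm),
                         scenario$photo)
  list(psi_leaf = psi_leaf, gs = gs, E = E, A = cp$A, Ci = cp$Ci,
       kleaf = kleaf_response(psi_leaf, scenario),
       residual = supply_demand_residual(psi_leaf, psi_soil, env, scenario),
       desiccated = FALSE)
}

#' Calibrate plant conductance to an operational leaf water potential
#'
#' Scales K_max (and the vulnerability slope with it, preserving P50) so the
#' steady state at field capacity yields the scenario's target operating
#' Psi_leaf within `tol` MPa. Mirrors the practice of adjusting plant
#' conductance so each plant type operates at its observed water potential.
#'
#' @param scenario A [plant_scenario()] with `target_psi_leaf` set.
#' @param env A [sim_environment()].
#' @param soil A [soil_state()]; field capacity is `theta_rel = 1`.
#' @param tol Tolerance on the achieved Psi_leaf, MPa.
#' @param scale_cap Largest admissible K_max multiplier.
#' @return The scenario with rescaled `K_max` and `vuln_slope`.
#' @export
calibrate_conductance <- function(scenario, env, soil = soil_state(),
                                  tol = 0.01, scale_cap = 1e4) {
  target <- scenario$target_psi_leaf
  if (is.null(target)) stop_invalid("scenario has no target_psi_leaf")
  psi_fc <- soil_water_potential(1, soil$psi_e, soil$b)
  if (target >= psi_fc || target <= scenario$psi_gs50) {
    stop(errorCondition(
      "target psi_leaf must lie between field-capacity psi_soil and psi_gs50",
      class = c("grasshydro_calibration_error", "grasshydro_error")))
  }
  achieved <- function(log_scale) {
    s <- rescale_kmax(scenario, exp(log_scale))
    solve_steady_state(psi_fc, env, s)$psi_leaf - target
  }
  lo <- log(1 / scale_cap); hi <- log(scale_cap)
  if (achieved(hi) < 0) {
    stop(errorCondition(
      "target psi_leaf unattainable below the conductance scale cap",
      class = c("grasshydro_calibration_error", "grasshydro_error")))
  }
  root <- uniroot(achieved, c(lo, hi), tol = 1e-10)$root
  out <- rescale_kmax(scenario, exp(root))
  if (abs(solve_steady_state(psi_fc, env, out)$psi_leaf - target) > tol) {
    stop(errorCondition("calibration did not reach the target psi_leaf",
                        class = c("grasshydro_calibration_error",
                                  "grasshydro_error")))
  }
  out
}

rescale_kmax <- function(scenario, scale) {
  scenario$K_max <- scenario$K_max * scale
  scenario$vuln_slope <- scenario$vuln_slope * scale
  scenario
}

#' Run a soil dry-down for one plant scenario
#'
#' Starting from field capacity, repeats: solve the steady state, transpire
#' E dt out of the soil bucket, update Psi_soil from the retention curve.
#' Stops when stomata are effectively closed (gs < 1% g_max), the soil
#' passes `psi_stop`, the bucket is exhausted, or `max_steps` is reached
#' (guards the zero-VPD case, where the soil never dries).
#'
#' @param scenario A [plant_scenario()].
#' @param env A [sim_environment()].
#' @param soil A [soil_state()].
#' @param dt Time step, hours (> 0).
#' @param psi_stop Stop threshold on Psi_soil, MPa.
#' @param max_steps Hard step cap.
#' @return `data.frame` of class `drydown_trajectory` with columns `step`,
#'   `time_h`, `theta_rel`, `psi_soil`, `psi_leaf`, `gs`, `E`, `A`, `kleaf`,
#'   `residual`.
#' @export
run_dry_down <- function(scenario, env, soil = soil_state(), dt = 0.5,
                         psi_stop = -3, max_steps = 5000) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  theta <- soil$theta_rel
  rows <- vector("list", max_steps)
  for (i in seq_len(max_steps)) {
    psi_soil <- soil_water_potential(theta, soil$psi_e, soil$b)
    st <- solve_steady_state(psi_soil, env, scenario)
    rows[[i]] <- data.frame(step = i, time_h = (i - 1) * dt,
                            theta_rel = theta, psi_soil = psi_soil,
                            psi_leaf = st$psi_leaf, gs = st$gs, E = st$E,
                            A = st$A, kleaf = st$kleaf,
                            residual = st$residual)
    if (st$gs < 0.01 * scenario$g_max || psi_soil < psi_stop ||
        st$desiccated) break
    # E mmol m^-2 s^-1 -> mol m^-2 over dt hours
    used <- st$E * 3600 * dt / 1000
    theta <- theta - used / soil$bucket_size
    if (theta <= 1e-4) break
    if (env$vpd == 0) break # nothing will ever change
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "scenario") <- scenario$label
  attr(out, "vpd") <- env$vpd
  class(out) <- c("drydown_trajectory", class(out))
  out
}

#' Default plant scenarios for the C3/C4 comparison
#'
#' Four plant types: reference C3 and C4, plus the two supply:demand swap
#' scenarios. C4 has lower g_max and, by keeping K_max equal to the C3
#' value, a twofold higher K_leaf:g_s (hydraulic hyper-efficiency). The swap
#' scenarios rescale K_max (not g_max) so each pathway runs with the other's
#' K_leaf:g_s ratio, preserving its own photosynthesis and stomatal
#' behaviour. Stomatal sensitivity (psi_gs50, c) and P50 are identical
#' across types, reflecting the statistically similar hydraulic
#' vulnerability of C3 and C4 grasses.
#'
#' @param g_max_c3,g_max_c4 Maximal stomatal conductances, mol m^-2 s^-1.
#' @param K_max_c3,K_max_c4 Maximum leaf hydraulic conductances,
#'   mmol m^-2 s^-1 MPa^-1.
#' @param psi_gs50 Water potential at half stomatal closure, MPa.
#' @param c Sigmoid steepness, MPa.
#' @param p50 Water potential at half hydraulic loss, MPa; sets the
#'   vulnerability slope a = K_max / (2 |P50|) per scenario.
#' @return Named list of four [plant_scenario()] objects.
#' @export
default_scenarios <- function(g_max_c3 = 0.32, g_max_c4 = 0.16,
                              K_max_c3 = 8, K_max_c4 = 8,
                              psi_gs50 = -1.5, c = 0.2, p50 = -1.8) {
  slope_for <- function(K) K / (2 * abs(p50))
  ratio_c3 <- K_max_c3 / g_max_c3
  ratio_c4 <- K_max_c4 / g_max_c4
  K_swap_c4 <- ratio_c3 * g_max_c4 # C4 plant with the C3 supply:demand ratio
  K_swap_c3 <- ratio_c4 * g_max_c3 # C3 plant with the C4 supply:demand ratio
  list(
    C3 = plant_scenario("C3", g_max_c3, psi_gs50, c, K_max_c3,
                        slope_for(K_max_c3), photo = c3_params()),
    C4 = plant_scenario("C4", g_max_c4, psi_gs50, c, K_max_c4,
                        slope_for(K_max_c4), photo = c4_params()),
    C3_with_C4_ratio = plant_scenario(
      "C3_with_C4_ratio", g_max_c3, psi_gs50, c, K_swap_c3,
      slope_for(K_swap_c3), photo = c3_params()),
    C4_with_C3_ratio = plant_scenario(
      "C4_with_C3_ratio", g_max_c4, psi_gs50, c, K_swap_c4,
      slope_for(K_swap_c4), photo = c4_params()))
}

#' Run the full simulation experiment
#'
#' All plant types crossed with the two VPD environments (0.5 kPa: 20 C at
#' 78.6% RH; 3 kPa: 30 C at 29.5% RH), each dried down from field capacity.
#' Also reports, per trajectory, the Psi_soil at which A drops below 90% of
#' its wet-soil value, and the Psi_soil at which A falls below the reference
#' C3 trajectory's A (interpolated on a common Psi_soil grid).
#'
#' @param scenarios Named list of [plant_scenario()]s.
#' @param environments Named list of [sim_environment()]s.
#' @param soil A [soil_state()].
#' @param dt Time step, hours.
#' @param reference Label of the reference scenario for A crossings.
#' @return List with `trajectories` (named list of
#'   [run_dry_down()] outputs, names `<scenario>@<env>`) and `summary`
#'   (`data.frame` of crossing points).
#' @export
scenario_suite <- function(scenarios = default_scenarios(),
                           environments = list(
                             vpd0.5 = sim_environment(20, 0.786),
                             vpd3 = sim_environment(30, 0.295)),
                           soil = soil_state(), dt = 0.5,
                           reference = "C3") {
  traj <- list()
  for (ev in names(environments)) {
    for (sc in names(scenarios)) {
      traj[[paste0(sc, "@", ev)]] <-
        run_dry_down(scenarios[[sc]], environments[[ev]], soil, dt = dt)
    }
  }
  summ <- do.call(rbind, lapply(names(environments), function(ev) {
    ref <- traj[[paste0(reference, "@", ev)]]
    do.call(rbind, lapply(names(scenarios), function(sc) {
      tr <- traj[[paste0(sc, "@", ev)]]
      data.frame(scenario = sc, environment = ev,
                 psi_soil_A90 = crossing_psi(tr$psi_soil, tr$A,
                                             0.9 * tr$A[1]),
                 psi_soil_below_ref = crossing_below_ref(tr, ref))
    }))
  }))
  rownames(summ) <- NULL
  list(trajectories = traj, summary = summ)
}

# first psi_soil (walking dry-ward) at which y drops below threshold
crossing_psi <- function(psi_soil, y, threshold) {
  below <- which(y < threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(psi_soil[1])
  # linear interpolation between the bracketing steps
  frac <- (threshold - y[i - 1]) / (y[i] - y[i - 1])
  psi_soil[i - 1] + frac * (psi_soil[i] - psi_soil[i - 1])
}

crossing_below_ref <- function(tr, ref) {
  lo <- max(min(tr$psi_soil), min(ref$psi_soil))
  hi <- min(max(tr$psi_soil), max(ref$psi_soil))
  if (lo >= hi) return(NA_real_)
  grid <- seq(hi, lo, length.out = 400)
  a <- approx(tr$psi_soil, tr$A, xout = grid, ties = mean)$y
  r <- approx(ref$psi_soil, ref$A, xout = grid, ties = mean)$y
  d <- a - r
  below <- which(d < 0)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(grid[1])
  frac <- (0 - d[i - 1]) / (d[i] - d[i - 1])
  grid[i - 1] + frac * (grid[i] - grid[i - 1])
}

#' Read a scenario suite configuration from YAML
#'
#' Schema: optional `environments:` (list of `{t_air, rh}`), `soil:`
#' (`{bucket_size, psi_e, b}`), `plants:` (list of [plant_scenario()]
#' fields, with `pathway: C3|C4` selecting the photosynthesis model and an
#' optional `photosynthesis:` override map), `dt`.
#'
#' @param path YAML file path.
#' @return List of arguments for [scenario_suite()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$environments)) {
    out$environments <- lapply(cfg$environments, function(e)
      do.call(sim_environment, e))
  }
  if (!is.null(cfg$soil)) out$soil <- do.call(soil_state, cfg$soil)
  if (!is.null(cfg$plants)) {
    out$scenarios <- lapply(names(cfg$plants), function(nm) {
      p <- cfg$plants[[nm]]
      photo_args <- p$photosynthesis %||% list()
      photo <- if (identical(p$pathway, "C4")) {
        do.call(c4_params, photo_args)
      } else do.call(c3_params, photo_args)
      p$pathway <- NULL; p$photosynthesis <- NULL
      do.call(plant_scenario, c(list(label = nm, photo = photo), p))
    })
    names(out$scenarios) <- names(cfg$plants)
  }
  if (!is.null(cfg$dt)) out$dt <- cfg$dt
  out
}
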