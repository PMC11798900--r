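# Steady-state assimilation models and their coupling to stomatal CO2
# diffusion. The C3 model is the Farquhar-type two-limitation form at fixed
# irradiance and 25 C; the C4 model is the enzyme-limited skeleton
# (PEP-carboxylation vs Rubisco-capacity limited), with mesophyll resistance
# and bundle-sheath leakiness treated as non-limiting, reflecting how the
# carbon concentrating mechanism removes mesophyll diffusion limitation.

#' C3 photosynthesis parameters
#'
#' Representative kinetic constants at 25 C. These are textbook defaults,
#' not species-specific estimates; override any of them per scenario.
#'
#' @param Vcmax Maximum carboxylation rate, umol m^-2 s^-1.
#' @param J Electron transport rate at the simulated irradiance,
#'   umol m^-2 s^-1.
#' @param Kc Michaelis constant for CO2, umol mol^-1.
#' @param Ko Michaelis constant for O2, mmol mol^-1.
#' @param O Oxygen mole fraction, mmol mol^-1.
#' @param gamma_star CO2 compensation point without day respiration,
#'   umol mol^-1.
#' @param Rd Day respiration, umol m^-2 s^-1.
#' @return List of class `c3_params`.
#' @export
c3_params <- function(Vcmax = 60, J = 120, Kc = 404.9, Ko = 278.4, O = 210,
                      gamma_star = 42.75, Rd = 1) {
  p <- list(Vcmax = Vcmax, J = J, Kc = Kc, Ko = Ko, O = O,
            gamma_star = gamma_star, Rd = Rd)
  for (nm in names(p)) check_positive(p[[nm]], nm)
  if (gamma_star >= Kc) stop_invalid("gamma_star must be < Kc")
  structure(c(p, list(pathway = "C3")), class = "c3_params")
}

#' C4 photosynthesis parameters
#'
#' Enzyme-limited C4 skeleton: the initial slope is set by PEP carboxylase
#' (Vpmax/Kp) and the plateau by Rubisco capacity in the bundle sheath
#' (Vcmax). `leakiness` is accepted for interface stability but currently
#' inert (treated as 0).
#'
#' @param Vpmax Maximum PEP carboxylation rate, umol m^-2 s^-1.
#' @param Kp Michaelis constant of PEP carboxylase for CO2, umol mol^-1.
#' @param Vcmax Bundle-sheath Rubisco capacity, umol m^-2 s^-1.
#' @param Rd Day respiration, umol m^-2 s^-1.
#' @param leakiness Bundle-sheath leak fraction; accepted but inert.
#' @return List of class `c4_params`.
#' @export
c4_params <- function(Vpmax = 55, Kp = 120, Vcmax = 45, Rd = 1,
                      leakiness = 0) {
  p <- list(Vpmax = Vpmax, Kp = Kp, Vcmax = Vcmax, Rd = Rd)
  for (nm in names(p)) check_positive(p[[nm]], nm)
  structure(c(p, list(leakiness = leakiness, pathway = "C4")),
            class = "c4_params")
}

#' Ambient air state
#'
#' @param Ca Ambient CO2 mole fraction, umol mol^-1.
#' @param Patm Atmospheric pressure, kPa.
#' @return List of class `air_state`.
#' @export
air_state <- function(Ca = 400, Patm = 101.3) {
  check_positive(Ca, "Ca")
  check_positive(Patm, "Patm")
  structure(list(Ca = Ca, Patm = Patm), class = "air_state")
}

#' Net C3 assimilation at a given intercellular CO2
#'
#' A = min(Wc, Wj) (1 - Gamma*/Ci) - Rd with the Rubisco-limited rate
#' Wc = Vcmax Ci / (Ci + Kc (1 + O/Ko)) and the RuBP-regeneration-limited
#' rate Wj = J Ci / (4 Ci + 8 Gamma*). Below the compensation point
#' photorespiratory release makes A more negative than -Rd; at Ci = 0 the
#' continuous limit -min(Vcmax/Kc', J/(8 Gamma*)) Gamma* - Rd is returned,
#' keeping A continuous and non-decreasing over the whole Ci range.
#'
#' @param Ci Intercellular CO2 mole fraction, umol mol^-1 (vectorised, >= 0).
#' @param p A [c3_params()] object.
#' @return Net assimilation, umol m^-2 s^-1.
#' @export
c3_assimilation <- function(Ci, p = c3_params()) {
  if (any(Ci < 0)) stop_invalid("Ci must be >= 0")
  kc_eff <- p$Kc * (1 + p$O / p$Ko)
  wc <- p$Vcmax * Ci / (Ci + kc_eff)
  wj <- p$J * Ci / (4 * Ci + 8 * p$gamma_star)
  gross <- pmin(wc, wj) * ifelse(Ci > 0, 1 - p$gamma_star / Ci, 1)
  lim0 <- -min(p$Vcmax / kc_eff, p$J / (8 * p$gamma_star)) * p$gamma_star
  ifelse(Ci > 0, gross, lim0) - p$Rd
}

#' Net C4 assimilation at a given intercellular CO2
#'
#' A = min(Vpmax Ci / (Ci + Kp), Vcmax) - Rd. The PEP-limited initial slope
#' (Vpmax/Kp) is much steeper than the C3 initial response at matched
#' capacities, which is what makes C4 gas exchange so sensitive to stomatal
#' closure.
#'
#' @param Ci Intercellular CO2 mole fraction, umol mol^-1 (vectorised, >= 0).
#' @param p A [c4_params()] object.
#' @return Net assimilation, umol m^-2 s^-1.
#' @export
c4_assimilation <- function(Ci, p = c4_params()) {
  if (any(Ci < 0)) stop_invalid("Ci must be >= 0")
  pmin(p$Vpmax * Ci / (Ci + p$Kp), p$Vcmax) - p$Rd
}

assimilation <- function(Ci, params) {
  if (inherits(params, "c3_params")) c3_assimilation(Ci, params)
  else if (inherits(params, "c4_params")) c4_assimilation(Ci, params)
  else stop_invalid("params must be c3_params or c4_params")
}

#' Couple assimilation demand to stomatal CO2 supply
#'
#' Solves for the intercellular CO2 at which the biochemical demand curve
#' A(Ci) intersects the stomatal supply line A = (gs/1.6)(Ca - Ci), where
#' 1.6 is the water:CO2 diffusivity ratio of stomata. The intersection is
#' unique because demand is non-decreasing and supply strictly decreasing in
#' Ci; it is found by bracketed root refinement to a residual below
#' `tol` umol m^-2 s^-1.
#'
#' With gs = 0 there is no flux through stomata; the returned state has
#' A clamped into [-Rd, 0] at the internal compensation point.
#'
#' @param gs Stomatal conductance to water vapour, mol m^-2 s^-1.
#' @param air An [air_state()] object.
#' @param params [c3_params()] or [c4_params()].
#' @param tol Residual tolerance, umol m^-2 s^-1.
#' @return List with `A` (umol m^-2 s^-1), `Ci` (umol mol^-1) and
#'   `residual`.
#' @export
couple_diffusion <- function(gs, air = air_state(), params = c3_params(),
                             tol = 1e-8) {
  if (gs < 0) stop_invalid("gs must be >= 0")
  g_c <- gs / 1.6
  f <- function(Ci) assimilation(Ci, params) - g_c * (air$Ca - Ci)
  if (gs == 0) {
    # no stomatal flux: Ci settles where net assimilation is zero (or stays
    # respiration-limited if A < 0 everywhere on [0, Ca])
    if (f(air$Ca) <= 0) {
      A <- max(min(assimilation(air$Ca, params), 0), -params$Rd)
      return(list(A = A, Ci = air$Ca, residual = 0))
    }
    root <- uniroot(f, c(0, air$Ca), tol = 1e-12)$root
    A <- assimilation(root, params)
    return(list(A = max(min(A, 0), -params$Rd), Ci = root, residual = 0))
  }
  lo <- 0
  hi <- air$Ca
  if (f(hi) <= 0) {
    # demand never reaches supply within [0, Ca] (cannot happen with positive
    # A(Ca), kept for safety): report the boundary state
    return(list(A = assimilation(hi, params), Ci = hi, residual = f(hi)))
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-13)$root
  # polish by bisection until the residual criterion itself is met
  a <- lo; b <- hi
  for (i in 1:200) {
    if (abs(f(root)) < tol) break
    if (f(root) > 0) b <- root else a <- root
    root <- (a + b) / 2
  }
  res <- f(root)
  if (abs(res) >= tol) {
    stop(errorCondition(
      sprintf("diffusion coupling did not converge (residual %.3e)", res),
      class = c("grasshydro_numerical_error", "grasshydro_error")))
  }
  list(A = assimilation(root, params), Ci = root, residual = res)
}

#' Read photosynthesis parameters from a YAML config
#'
#' Expects a top-level `photosynthesis:` block with `c3:` and/or `c4:` maps;
#' fields missing from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return List with `c3` ([c3_params()]) and `c4` ([c4_params()]).
#' @export
read_photosynthesis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ph <- cfg$photosynthesis %||% cfg
  list(c3 = do.call(c3_params, ph$c3 %||% list()),
       c4 = do.call(c4_params, ph$c4 %||% list()))
}
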