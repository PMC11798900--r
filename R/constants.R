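#' Physical constants for hydraulic calculations
#'
#' Bundles the two constants every conductance calculation needs: the dynamic
#' viscosity of liquid water at 25 degrees C expressed in MPa s, and the molar
#' density of liquid water used to convert volumetric conductivities
#' (m^4 MPa^-1 s^-1) to the molar units conventional in leaf hydraulics
#' (mmol m s^-1 MPa^-1).
#'
#' @param water_viscosity Dynamic viscosity of water at 25 C, MPa s.
#' @param molar_volume mmol of water per m^3 of liquid water.
#' @return An object of class `hydro_constants`.
#' @examples
#' hydro_constants()
#' @export
hydro_constants <- function(water_viscosity = 8.9e-10,
                            molar_volume = 5.556e7) {
  check_positive(water_viscosity, "water_viscosity")
  check_positive(molar_volume, "molar_volume")
  structure(list(water_viscosity = water_viscosity,
                 molar_volume = molar_volume),
            class = "hydro_constants")
}

# unit helpers: all anatomy inputs arrive in field units (um, mm mm^-2, m)
um_to_m <- function(x) x * 1e-6
mm_per_mm2_to_per_m <- function(x) x * 1e3
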