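#' Unit conversions
#'
#' Convenience conversions between the units customary in nanopore work
#' (molar concentrations, dipoles in e nm or debye) and the SI values used
#' internally by every model function.
#'
#' @param c_molar Concentration in mol/L.
#' @return `molarity_to_density()`: particle number density in 1/m^3.
#' @examples
#' molarity_to_density(40e-6)       # 40 uM -> ~2.41e22 m^-3
#' e_nm_to_SI(12)                   # 12 e nm -> C m
#' dipole_to_debye(e_nm_to_SI(12))  # ~576 D
#' dumbbell_dipole(2 * pc_constants$e, 4e-9)  # +-2e ends, 4 nm apart
#' @export
molarity_to_density <- function(c_molar) {
  c_molar * 1e3 * pc_constants$NA_avogadro
}

#' @rdname molarity_to_density
#' @param p_enm Dipole moment in units of e nm.
#' @return `e_nm_to_SI()`: dipole moment in C m.
#' @export
e_nm_to_SI <- function(p_enm) {
  p_enm * pc_constants$e * 1e-9
}

#' @rdname molarity_to_density
#' @param p_SI Dipole moment in C m.
#' @return `dipole_to_debye()`: dipole moment in debye.
#' @export
dipole_to_debye <- function(p_SI) {
  p_SI / pc_constants$debye
}

#' @rdname molarity_to_density
#' @param q_end Magnitude of the charge at each end of a dumbbell, C.
#' @param d Separation of the two end charges, m.
#' @return `dumbbell_dipole()`: dipole moment `q_end * d` in C m.
#' @export
dumbbell_dipole <- function(q_end, d) {
  q_end * d
}

# --- quantity parsing for scenario files ------------------------------------

# Conversion table: unit string -> list(dimension, factor to SI).
# "e" charges, "kBT" energies and molar concentrations get special factors.
.unit_table <- local({
  e <- 1.602176634e-19
  NAv <- 6.02214076e23
  tbl <- list(
    # length
    "m" = c("length", 1), "nm" = c("length", 1e-9), "um" = c("length", 1e-6),
    "A" = c("length", 1e-10),
    # voltage
    "V" = c("voltage", 1), "mV" = c("voltage", 1e-3),
    # charge
    "C" = c("charge", 1), "e" = c("charge", e),
    # surface charge density
    "C/m^2" = c("surface_charge", 1), "mC/m^2" = c("surface_charge", 1e-3),
    "e/nm^2" = c("surface_charge", e / 1e-18),
    # conductivity
    "S/m" = c("conductivity", 1), "mS/cm" = c("conductivity", 0.1),
    # conductance
    "S" = c("conductance", 1), "nS" = c("conductance", 1e-9),
    "pS" = c("conductance", 1e-12),
    # electroosmotic conductance (volumetric flow per volt)
    "m^3/(s*V)" = c("eo_conductance", 1), "m^3/s/V" = c("eo_conductance", 1),
    # dynamic viscosity
    "Pa*s" = c("viscosity", 1), "mPa*s" = c("viscosity", 1e-3),
    # kinematic viscosity / diffusivity
    "m^2/s" = c("kinematic", 1), "cm^2/s" = c("kinematic", 1e-4),
    # density
    "kg/m^3" = c("density", 1), "g/cm^3" = c("density", 1e3),
    # temperature
    "K" = c("temperature", 1),
    # concentration (number density)
    "1/m^3" = c("concentration", 1), "m^-3" = c("concentration", 1),
    "M" = c("concentration", 1e3 * NAv), "mM" = c("concentration", NAv),
    "uM" = c("concentration", 1e-3 * NAv), "nM" = c("concentration", 1e-6 * NAv),
    # dipole
    "C*m" = c("dipole", 1), "e*nm" = c("dipole", e * 1e-9),
    "D" = c("dipole", 3.33564e-30),
    # energy in thermal units (dimensionless barrier heights)
    "kBT" = c("energy_kBT", 1),
    # rates / misc
    "1" = c("dimensionless", 1),
    "s" = c("time", 1), "ms" = c("time", 1e-3),
    "Hz" = c("frequency", 1), "1/s" = c("frequency", 1),
    "m/s" = c("speed", 1)
  )
  tbl
})

#' Parse a value + unit pair into SI
#'
#' Scenario files give every quantity as `{value: ..., unit: "..."}`.  This
#' converts to the SI value used internally, checking that the unit belongs
#' to the expected dimension.
#'
#' @param x A list with elements `value` and `unit`, or a bare number (taken
#'   as already-SI when `dimension` allows it).
#' @param dimension Expected dimension label, e.g. `"length"`; `NULL` skips
#'   the check.
#' @param field Field name used in error messages.
#' @return Numeric scalar in SI units.
#' @export
parse_quantity <- function(x, dimension = NULL, field = "quantity") {
  if (is.numeric(x) && length(x) == 1L) {
    return(as.numeric(x))
  }
  if (!is.list(x) || is.null(x$value) || is.null(x$unit)) {
    stop(sprintf("field '%s': expected a number or {value, unit}", field),
         call. = FALSE)
  }
  u <- as.character(x$unit)
  if (!nzchar(u)) u <- "1"
  entry <- .unit_table[[u]]
  if (is.null(entry)) {
    stop(sprintf("field '%s': unknown unit '%s'", field, u), call. = FALSE)
  }
  if (!is.null(dimension) && entry[[1]] != dimension) {
    stop(sprintf("field '%s': unit '%s' has dimension '%s', expected '%s'",
                 field, u, entry[[1]], dimension), call. = FALSE)
  }
  as.numeric(x$value) * as.numeric(entry[[2]])
}
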