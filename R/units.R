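# Internal unit system is CGS (cm, s, g). Pressures cross the package
# boundary in mmHg only; everything downstream of I/O is dyn/cm^2.

#' Pressure unit conversion constant
#'
#' One millimetre of mercury expressed in dyn/cm^2 (barye).
#' @export
MMHG_TO_DYN_CM2 <- 1333.22

#' Convert pressure from mmHg to dyn/cm^2
#'
#' @param p Pressure in mmHg (numeric vector).
#' @return Pressure in dyn/cm^2.
#' @examples
#' mmHg_to_cgs(1)     # 1333.22
#' mmHg_to_cgs(91.4)  # a typical mean arterial pressure in CGS
#' @export
mmHg_to_cgs <- function(p) {
  stopifnot(is.numeric(p))
  p * MMHG_TO_DYN_CM2
}

#' Convert pressure from dyn/cm^2 to mmHg
#'
#' Exact inverse of [mmHg_to_cgs()]; the round trip is the identity to
#' machine precision.
#' @param p Pressure in dyn/cm^2.
#' @return Pressure in mmHg.
#' @export
cgs_to_mmHg <- function(p) {
  stopifnot(is.numeric(p))
  p / MMHG_TO_DYN_CM2
}

#' Blood fluid properties
#'
#' Newtonian fluid model: dynamic viscosity in Poise (g cm^-1 s^-1) and
#' density in g/cm^3. Defaults are the standard values for blood used in
#' carotid CFD (mu = 0.04 Poise, rho = 1.06 g/cm^3).
#'
#' @param viscosity Dynamic viscosity, Poise. Must be > 0.
#' @param density Density, g/cm^3. Must be > 0.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 0.04, density = 1.06) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be a single positive number (Poise)", call. = FALSE)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) || density <= 0)
    stop("`density` must be a single positive number (g/cm^3)", call. = FALSE)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: mu = %g Poise, rho = %g g/cm^3\n", x$viscosity, x$density))
  invisible(x)
}

#' Reynolds number
#'
#' Re = rho * v * D / mu in CGS units. Carotid flows of interest here are
#' laminar (Re roughly 100-350).
#'
#' @param mean_speed Characteristic speed, cm/s.
#' @param diameter Characteristic diameter, cm.
#' @param fluid A [fluid_properties()] object.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(mean_speed, diameter, fluid = fluid_properties()) {
  stopifnot(is.numeric(mean_speed), is.numeric(diameter), mean_speed >= 0, diameter > 0)
  fluid$density * mean_speed * diameter / fluid$viscosity
}
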