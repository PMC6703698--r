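# Unit conversion constants.  All internal solver arithmetic is SI
# (Pa, m, m^2, m^3/s); user-facing interfaces speak mmHg, mm and ml/s.

MMHG_PA <- 133.322

#' Physical properties of blood (and gravity)
#'
#' Container for the fluid constants used throughout the model.  Defaults are
#' the values used for equine blood: density 1050 kg/m^3, dynamic viscosity
#' 0.004 Pa.s, gravitational acceleration 9.81 m/s^2.
#'
#' @param density Blood density in kg/m^3.
#' @param viscosity Dynamic viscosity in Pa.s.
#' @param gravity Gravitational acceleration in m/s^2.
#' @return An object of class `blood_properties`.
#' @examples
#' blood_properties()
#' @export
blood_properties <- function(density = 1050, viscosity = 0.004, gravity = 9.81) {
  stopifnot(density > 0, viscosity > 0, gravity >= 0)
  structure(
    list(density = density, viscosity = viscosity, gravity = gravity),
    class = "blood_properties"
  )
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf(
    "<blood_properties> rho = %g kg/m^3, mu = %g Pa.s, g = %g m/s^2\n",
    x$density, x$viscosity, x$gravity
  ))
  invisible(x)
}

mmhg_to_pa <- function(p) p * MMHG_PA
pa_to_mmhg <- function(p) p / MMHG_PA

# mmHg.s/ml <-> Pa.s/m^3  (1 mmHg.s/ml = 133.322e6 Pa.s/m^3)
rmmhg_to_si <- function(r) r * MMHG_PA / 1e-6
rsi_to_mmhg <- function(r) r * 1e-6 / MMHG_PA

# ml/mmHg <-> m^3/Pa
cmmhg_to_si <- function(cc) cc * 1e-6 / MMHG_PA
csi_to_mmhg <- function(cc) cc * MMHG_PA / 1e-6
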