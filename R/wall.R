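#' Nonlinear elastic arterial wall law
#'
#' Constitutive law linking intra-arterial pressure and cross-sectional area.
#' Area compliance is the product of a location-dependent part `Cd` (set by the
#' local mean lumen diameter through an empirical inverse power law for pulse
#' wave velocity, `PWV = a2 / d^b2`) and a pressure-dependent bell-shaped part
#' `Cp(P) = a1 + b1 / (1 + ((P - p_max_c) / p_width)^2)`:
#'
#' `C_A(A, d, P) = distensibility_scale * A / (rho * PWV(d)^2) * Cp(P)`
#'
#' Defaults are the equine-tuned constants: `a1 = 0.76`, `b1 = 5`,
#' `p_max_c = 10` mmHg, `p_width = 21` mmHg, `a2 = 13.3`, `b2 = 0.3`,
#' reference pressure 100 mmHg and a global distensibility scale factor 0.75.
#'
#' @param a1,b1 Dimensionless constants of the pressure-dependent factor.
#' @param p_max_c Pressure of maximal compliance, mmHg.
#' @param p_width Width of the compliance bell, mmHg.
#' @param a2 PWV scale constant, m/s at a diameter of 1 mm.
#' @param b2 Dimensionless exponent of the inverse power law.
#' @param p_ref Reference pressure, mmHg.
#' @param distensibility_scale Global factor applied to all distensibilities.
#' @return An object of class `compliance_law`.
#' @examples
#' law <- compliance_law()
#' pwv_of_diameter(68, law)
#' @export
compliance_law <- function(a1 = 0.76, b1 = 5, p_max_c = 10, p_width = 21,
                           a2 = 13.3, b2 = 0.3, p_ref = 100,
                           distensibility_scale = 0.75) {
  stopifnot(a1 > 0, b1 > 0, p_width > 0, a2 > 0, distensibility_scale > 0)
  structure(
    list(
      a1 = a1, b1 = b1, p_max_c = p_max_c, p_width = p_width,
      a2 = a2, b2 = b2, p_ref = p_ref,
      distensibility_scale = distensibility_scale
    ),
    class = "compliance_law"
  )
}

#' @export
print.compliance_law <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<compliance_law> Cp(P) = %g + %g/(1+((P-%g)/%g)^2)  [P in mmHg]\n",
      "  PWV(d) = %g / d^%g m/s (d in mm), scale = %g, Pref = %g mmHg\n"
    ),
    x$a1, x$b1, x$p_max_c, x$p_width, x$a2, x$b2,
    x$distensibility_scale, x$p_ref
  ))
  invisible(x)
}

#' Pulse wave velocity from the local mean diameter
#'
#' Empirical inverse power curve `PWV = a2 / d^b2` giving the reference-pressure
#' pulse wave velocity for a vessel of mean lumen diameter `d` (in mm), before
#' the global distensibility scaling is applied.
#'
#' @param d_mean Mean lumen diameter in mm.
#' @param law A [compliance_law()].
#' @return PWV in m/s.
#' @examples
#' pwv_of_diameter(1)    # 13.3 m/s
#' pwv_of_diameter(68)   # about 3.75 m/s, ascending aorta
#' @export
pwv_of_diameter <- function(d_mean, law = compliance_law()) {
  stopifnot(all(d_mean > 0))
  law$a2 / d_mean^law$b2
}

#' Pressure-dependent compliance factor
#'
#' The bell-shaped factor `Cp(P) = a1 + b1 / (1 + ((P - p_max_c)/p_width)^2)`,
#' peaking at `P = p_max_c` with value `a1 + b1` and tending to `a1` far from
#' the peak.
#'
#' @param p Pressure in mmHg (vectorised).
#' @param law A [compliance_law()].
#' @return Dimensionless factor.
#' @examples
#' pressure_compliance_factor(10)    # a1 + b1 = 5.76
#' pressure_compliance_factor(100)   # about 1.02
#' @export
pressure_compliance_factor <- function(p, law = compliance_law()) {
  law$a1 + law$b1 / (1 + ((p - law$p_max_c) / law$p_width)^2)
}

# Antiderivative of Cp with respect to pressure (mmHg in, mmHg out).
cp_integral <- function(p, law) {
  law$a1 * p + law$b1 * law$p_width * atan((p - law$p_max_c) / law$p_width)
}

#' Area compliance of a vessel
#'
#' `C_A = distensibility_scale * A / (rho * PWV(d)^2) * Cp(P)`.  When a
#' reference distensibility (as tabulated for the packaged equine segments,
#' in 1e-3/mmHg at the reference pressure) is supplied it replaces the
#' diameter-based part, i.e. `C_A = A * D_ref * Cp(P)` with `D_ref` converted
#' to 1/Pa; the tabulated column already carries the global 0.75 factor.
#'
#' @param area Cross-sectional area in m^2.
#' @param d_mean Mean lumen diameter in mm (used when `distensibility_ref` is
#'   `NULL`).
#' @param p Pressure in mmHg.
#' @param law A [compliance_law()].
#' @param blood A [blood_properties()].
#' @param distensibility_ref Optional tabulated distensibility in 1e-3/mmHg.
#' @return Area compliance in m^2/Pa.
#' @export
area_compliance <- function(area, d_mean, p, law = compliance_law(),
                            blood = blood_properties(),
                            distensibility_ref = NULL) {
  stopifnot(all(area > 0))
  delta <- wall_delta_si(law, blood, d_mean, distensibility_ref)
  area * delta * pressure_compliance_factor(p, law)
}

# Distensibility-per-Cp at reference, in 1/Pa: the "Cd/A" part of the law.
wall_delta_si <- function(law, blood, d_mean = NULL, distensibility_ref = NULL) {
  if (!is.null(distensibility_ref)) {
    distensibility_ref * 1e-3 / MMHG_PA
  } else {
    pwv <- pwv_of_diameter(d_mean, law)
    law$distensibility_scale / (blood$density * pwv^2)
  }
}

#' Area as a function of pressure (and its inverse)
#'
#' Integrating the wall law `dA/dP = A * delta * Cp(P)` from the reference
#' anchor `(p_ref, area_ref)` gives the closed form
#' `A(P) = area_ref * exp(delta * (G(P) - G(p_ref)))` with
#' `G(P) = a1 P + b1 p_width atan((P - p_max_c)/p_width)`; `G` is strictly
#' increasing so the law is globally invertible.  `pressure_from_area()`
#' inverts it with a Newton iteration on `G`.
#'
#' @param p Pressure in mmHg.
#' @param area Cross-sectional area in m^2.
#' @param area_ref Reference area (at `law$p_ref`) in m^2.
#' @param delta Distensibility-per-Cp at reference, 1/mmHg (e.g. the packaged
#'   distensibility column times 1e-3).
#' @param law A [compliance_law()].
#' @return `area_from_pressure()` returns area in m^2; `pressure_from_area()`
#'   returns pressure in mmHg.
#' @examples
#' law <- compliance_law()
#' a <- area_from_pressure(120, area_ref = 1e-4, delta = 6.85e-3)
#' pressure_from_area(a, area_ref = 1e-4, delta = 6.85e-3)  # 120
#' @export
area_from_pressure <- function(p, area_ref, delta, law = compliance_law()) {
  area_ref * exp(delta * (cp_integral(p, law) - cp_integral(law$p_ref, law)))
}

#' @rdname area_from_pressure
#' @export
pressure_from_area <- function(area, area_ref, delta, law = compliance_law()) {
  stopifnot(all(area > 0))
  g_target <- cp_integral(law$p_ref, law) + log(area / area_ref) / delta
  # bisection-safeguarded Newton on the strictly increasing G(P): plain
  # Newton can overshoot across the compliance bell
  vapply(g_target, function(gt) {
    lo <- law$p_max_c - 10
    hi <- law$p_max_c + 10
    while (cp_integral(lo, law) > gt) lo <- lo - 2 * (law$p_max_c + 10 - lo)
    while (cp_integral(hi, law) < gt) hi <- hi + 2 * (hi - law$p_max_c + 10)
    p <- (lo + hi) / 2
    for (i in 1:200) {
      f <- cp_integral(p, law) - gt
      if (f > 0) hi <- p else lo <- p
      step <- f / pressure_compliance_factor(p, law)
      p_new <- p - step
      if (p_new <= lo || p_new >= hi) p_new <- (lo + hi) / 2
      if (abs(p_new - p) < 1e-12 * max(1, abs(p_new))) {
        p <- p_new
        break
      }
      p <- p_new
    }
    p
  }, numeric(1))
}

#' Local pulse wave velocity at a working pressure
#'
#' `PWV = sqrt(A / (rho * C_A))` evaluated from the wall law.
#'
#' @inheritParams area_from_pressure
#' @param blood A [blood_properties()].
#' @return PWV in m/s.
#' @export
local_pwv <- function(p, area_ref, delta, law = compliance_law(),
                      blood = blood_properties()) {
  delta_si <- delta / MMHG_PA
  sqrt(1 / (blood$density * delta_si * pressure_compliance_factor(p, law)))
}
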