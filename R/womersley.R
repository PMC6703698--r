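# Witzig-Womersley oscillatory flow theory: complex Bessel machinery,
# velocity profiles, wall shear and the convective-acceleration integrand.

#' Womersley number
#'
#' `alpha = R * sqrt(rho * 2 * pi * f / mu)`: the ratio of pulsatile inertia
#' to viscous forces for a vessel of radius `R` at frequency `f`.
#'
#' @param radius Lumen radius in m.
#' @param freq Frequency in Hz (the heart-rate fundamental, or a harmonic).
#' @param blood A [blood_properties()].
#' @return Dimensionless Womersley number.
#' @examples
#' womersley_number(0.0338, 40 / 60)  # proximal aorta at 40 bpm, about 35.5
#' @export
womersley_number <- function(radius, freq, blood = blood_properties()) {
  stopifnot(all(radius > 0), all(freq > 0))
  radius * sqrt(blood$density * 2 * pi * freq / blood$viscosity)
}

# ---- complex Bessel functions of the first kind, orders 0 and 1 ------------
#
# Arguments here are Lambda = alpha * i^(3/2) (|arg z| = 3pi/4) and scaled
# versions Lambda * xi.  base::besselJ is real-only, so J0/J1 are evaluated
# from the ascending series for moderate |z| and from Hankel's asymptotic
# expansion for large |z|.  Both branches support an exponential scaling
# (multiplication by exp(-|Im z|)) so that ratios of scaled values never
# overflow at extreme Womersley numbers.

besselj01_complex <- function(z, scaled = FALSE) {
  z <- as.complex(z)
  out0 <- out1 <- complex(length(z))
  big <- Mod(z) > 14
  if (any(!big)) {
    zz <- z[!big]
    q <- -(zz * zz) / 4
    t0 <- rep(1 + 0i, length(zz))
    t1 <- rep(1 + 0i, length(zz))
    s0 <- t0
    s1 <- t1
    for (k in 1:60) {
      t0 <- t0 * q / (k * k)
      t1 <- t1 * q / (k * (k + 1))
      s0 <- s0 + t0
      s1 <- s1 + t1
    }
    out0[!big] <- s0
    out1[!big] <- (zz / 2) * s1
  }
  if (any(big)) {
    zz <- z[big]
    hank <- function(nu, zz) {
      mu <- 4 * nu^2
      a <- rep(1 + 0i, length(zz))
      p <- rep(1 + 0i, length(zz))
      q <- rep(0 + 0i, length(zz))
      # Hankel expansion: a_k = prod(mu - (2j-1)^2)/(k! 8^k), alternating
      # between P (even k) and Q (odd k)
      for (k in 1:8) {
        a <- a * (mu - (2 * k - 1)^2) / (k * 8) / zz
        if (k %% 2 == 1) {
          q <- q + a * (-1)^((k - 1) / 2)
        } else {
          p <- p + a * (-1)^(k / 2)
        }
      }
      chi <- zz - nu * pi / 2 - pi / 4
      sqrt(2 / (pi * zz)) * (p * cos(chi) - q * sin(chi))
    }
    out0[big] <- hank(0, zz)
    out1[big] <- hank(1, zz)
  }
  if (scaled) {
    sc <- exp(-abs(Im(z)))
    out0 <- out0 * sc
    out1 <- out1 * sc
  }
  if (any(!is.finite(out0)) || any(!is.finite(out1))) {
    stop("Bessel evaluation did not produce finite values; use scaled = TRUE")
  }
  list(j0 = out0, j1 = out1)
}

# Lambda = alpha * i^(3/2)
.lambda_of_alpha <- function(alpha) alpha * complex(real = -1, imaginary = 1) / sqrt(2)

# Womersley denominator D = 1 - 2 J1(L)/(L J0(L)), evaluated from scaled
# Bessel values (the common scale cancels in the ratio).
.womersley_denominator <- function(alpha) {
  lam <- .lambda_of_alpha(alpha)
  b <- besselj01_complex(lam, scaled = TRUE)
  1 - 2 * b$j1 / (lam * b$j0)
}

# Radial profile factor [1 - J0(L xi)/J0(L)] / D for one harmonic, vectorised
# over xi.  Scaling: J0(L xi) e^{-|Im L xi|} / (J0(L) e^{-|Im L|}) times
# e^{|Im L xi| - |Im L|} (a decaying factor since xi <= 1).
.womersley_profile_factor <- function(alpha, xi) {
  lam <- .lambda_of_alpha(alpha)
  d <- .womersley_denominator(alpha)
  num <- besselj01_complex(lam * xi, scaled = TRUE)$j0
  den <- besselj01_complex(lam, scaled = TRUE)$j0
  ratio <- num / den * exp(abs(Im(lam)) * (xi - 1))
  (1 - ratio) / d
}

# Wall-shear transfer factor: tau_n = mu Qn/(pi R^3) * [L J1(L)/J0(L)] / D
.womersley_shear_factor <- function(alpha) {
  lam <- .lambda_of_alpha(alpha)
  b <- besselj01_complex(lam, scaled = TRUE)
  (lam * b$j1 / b$j0) / .womersley_denominator(alpha)
}

#' Decompose a periodic flow waveform into harmonics
#'
#' Fourier decomposition of one cardiac cycle of flow into a steady (mean)
#' term and `n_harmonics` complex harmonic amplitudes, the input the
#' Witzig-Womersley profile and friction formulas require.
#'
#' @param q Flow samples over exactly one period (uniform grid, the last
#'   sample being the one before the period repeats), any units.
#' @param period Cycle duration in s.
#' @param n_harmonics Number of oscillatory harmonics retained.
#' @return A `flow_harmonics` object: `q_mean`, complex `qn`, fundamental
#'   angular frequency `omega`, `period`.
#' @export
flow_harmonics <- function(q, period, n_harmonics = 20) {
  n <- length(q)
  stopifnot(n > 2 * n_harmonics, period > 0)
  coef <- stats::fft(q) / n
  structure(
    list(
      q_mean = Re(coef[1]),
      qn = 2 * coef[seq_len(n_harmonics) + 1],
      omega = 2 * pi / period,
      period = period
    ),
    class = "flow_harmonics"
  )
}

#' Reconstruct a flow waveform from its harmonics
#'
#' @param harmonics A [flow_harmonics()] object.
#' @param t Times at which to evaluate, s.
#' @return Flow values in the units of the decomposed series.
#' @export
harmonics_to_flow <- function(harmonics, t) {
  out <- rep(harmonics$q_mean, length(t))
  for (k in seq_along(harmonics$qn)) {
    out <- out + Re(harmonics$qn[k] * exp(1i * k * harmonics$omega * t))
  }
  out
}

#' Witzig-Womersley axial velocity profile
#'
#' Velocity profile `u(r, t)` reconstructed from flow harmonics: a parabolic
#' Poiseuille contribution from the steady term plus Womersley profiles (flat
#' core, thin oscillating wall layer at large Womersley number) for each
#' harmonic.
#'
#' @param harmonics A [flow_harmonics()] with flow in m^3/s.
#' @param radius Lumen radius in m.
#' @param r_over_r Relative radial positions in `[0, 1]`.
#' @param t Times in s (vectorised).
#' @param blood A [blood_properties()].
#' @return A matrix of axial velocities (m/s), `length(r_over_r)` rows by
#'   `length(t)` columns.
#' @export
velocity_profile <- function(harmonics, radius, r_over_r, t,
                             blood = blood_properties()) {
  stopifnot(radius > 0, all(r_over_r >= 0), all(r_over_r <= 1))
  area <- pi * radius^2
  u <- outer(
    2 * harmonics$q_mean / area * (1 - r_over_r^2),
    rep(1, length(t))
  )
  f0 <- harmonics$omega / (2 * pi)
  for (k in seq_along(harmonics$qn)) {
    alpha_k <- womersley_number(radius, k * f0, blood)
    prof <- .womersley_profile_factor(alpha_k, r_over_r)
    phase <- exp(1i * k * harmonics$omega * t)
    u <- u + Re(outer(prof * harmonics$qn[k] / area, phase))
  }
  u
}

#' Wall shear stress from flow harmonics
#'
#' `tau(t)` at the lumen wall: the Poiseuille term `-4 mu Q1 / (pi R^3)` plus
#' the Womersley harmonic terms.
#'
#' @inheritParams velocity_profile
#' @return Shear stress in Pa at each `t` (negative for forward flow).
#' @export
wall_shear <- function(harmonics, radius, t, blood = blood_properties()) {
  stopifnot(radius > 0)
  tau <- rep(-4 * blood$viscosity * harmonics$q_mean / (pi * radius^3), length(t))
  f0 <- harmonics$omega / (2 * pi)
  for (k in seq_along(harmonics$qn)) {
    alpha_k <- womersley_number(radius, k * f0, blood)
    fac <- .womersley_shear_factor(alpha_k)
    tau <- tau + Re(
      blood$viscosity / (pi * radius^3) * harmonics$qn[k] * fac *
        exp(1i * k * harmonics$omega * t)
    )
  }
  tau
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch on the Jacobi matrix).
gauss_legendre_01 <- function(n) {
  if (n == 1) {
    return(list(x = 0.5, w = 1))
  }
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  jac <- matrix(0, n, n)
  jac[cbind(k, k + 1)] <- beta
  jac[cbind(k + 1, k)] <- beta
  e <- eigen(jac, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1, ]^2)
  list(x = (x + 1) / 2, w = w / 2)
}

#' Momentum-flux integral of a velocity profile
#'
#' Evaluates `int_A u^2 dA` over the lumen from the Womersley profile by
#' Gauss-Legendre quadrature in the radial coordinate; for a flat profile
#' this equals `Q^2 / A`.
#'
#' @inheritParams velocity_profile
#' @param n_radial Number of radial quadrature points.
#' @return Values of the integral (m^4/s^2) at each `t`.
#' @export
momentum_flux_integral <- function(harmonics, radius, t,
                                   blood = blood_properties(), n_radial = 64) {
  gl <- gauss_legendre_01(n_radial)
  u <- velocity_profile(harmonics, radius, gl$x, t, blood)
  # int u^2 2 pi r dr = 2 pi R^2 int u(xi)^2 xi dxi
  as.numeric(2 * pi * radius^2 * crossprod(gl$w * gl$x, u^2))
}

#' Flat-profile momentum flux
#'
#' The Stergiopulos flat-profile closure `int_A u^2 dA = Q^2 / A`, used for
#' low Womersley number vessels (`alpha <= 3`).
#'
#' @param q Flow in m^3/s.
#' @param area Cross-sectional area in m^2.
#' @return Momentum flux in m^4/s^2.
#' @export
flat_momentum_flux <- function(q, area) q^2 / area
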