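blood <- blood_properties()

test_that("Womersley number matches the closed form and Table values", {
  # proximal aorta at 40 bpm, mid-tapered radius of the ascending aorta
  r_prox <- (68.18 + 67.39) / 4 / 1000
  expect_equal(womersley_number(r_prox, 40 / 60, blood), 35.47, tolerance = 0.02)
  expect_equal(
    womersley_number(2 * r_prox, 40 / 60, blood),
    2 * womersley_number(r_prox, 40 / 60, blood)
  )
  expect_equal(
    womersley_number(0.01, 2, blood),
    0.01 * sqrt(1050 * 2 * pi * 2 / 0.004)
  )
})

test_that("complex Bessel evaluation agrees with an independent quadrature oracle", {
  # J_n(z) = (1/pi) Int_0^pi cos(n t - z sin t) dt, valid for complex z by
  # analytic continuation of the integrand (evaluated via explicit complex
  # arithmetic under integrate())
  j_int <- function(z, n) {
    re <- stats::integrate(function(t) Re(cos(n * t - z * sin(t))), 0, pi,
      rel.tol = 1e-12
    )$value
    im <- stats::integrate(function(t) Im(cos(n * t - z * sin(t))), 0, pi,
      rel.tol = 1e-12
    )$value
    complex(real = re, imaginary = im) / pi
  }
  for (alpha in c(0.5, 3, 10, 16)) {
    z <- alpha * complex(real = -1, imaginary = 1) / sqrt(2)
    b <- equihemo:::besselj01_complex(z)
    expect_equal(b$j0, j_int(z, 0), tolerance = 1e-7)
    expect_equal(b$j1, j_int(z, 1), tolerance = 1e-7)
  }
})

test_that("steady harmonics give an exact Poiseuille profile", {
  h <- structure(
    list(q_mean = 1e-4, qn = complex(0), omega = 2 * pi / 1.5, period = 1.5),
    class = "flow_harmonics"
  )
  r <- 0.01
  u <- velocity_profile(h, r, c(0, 0.5, 1), t = 0, blood = blood)
  u_centre <- 2 * 1e-4 / (pi * r^2)
  expect_equal(u[, 1], u_centre * c(1, 0.75, 0), tolerance = 1e-12)
  tau <- wall_shear(h, r, t = 0, blood = blood)
  expect_equal(tau, -4 * blood$viscosity * 1e-4 / (pi * r^3))
})

test_that("profile integrates to the flow waveform at every instant", {
  set.seed(7)
  n <- 300
  q <- 5e-4 + 3e-4 * sin(2 * pi * (0:(n - 1)) / n) +
    1e-4 * cos(6 * pi * (0:(n - 1)) / n + 0.4)
  h <- flow_harmonics(q, period = 1.5, n_harmonics = 15)
  r <- 0.0338
  tt <- seq(0, 1.5, length.out = 13)
  gl <- equihemo:::gauss_legendre_01(64)
  u <- velocity_profile(h, r, gl$x, tt, blood)
  q_int <- as.numeric(2 * pi * r^2 * crossprod(gl$w * gl$x, u))
  q_true <- harmonics_to_flow(h, tt)
  expect_lt(max(abs(q_int - q_true)) / max(abs(q_true)), 1e-6)
})

test_that("single harmonic at alpha = 10 shows the flat core and wall overshoot", {
  f <- 10^2 * blood$viscosity / (blood$density * 2 * pi * 0.01^2)  # alpha = 10 at R = 1 cm
  h <- structure(
    list(q_mean = 0, qn = complex(real = 1e-4), omega = 2 * pi * f, period = 1 / f),
    class = "flow_harmonics"
  )
  xi <- seq(0, 1, length.out = 201)
  u <- velocity_profile(h, 0.01, xi, t = seq(0, 1 / f, length.out = 33), blood)
  env <- apply(abs(u), 1, max)
  # envelope nearly uniform in the core, overshooting near the wall
  expect_lt(diff(range(env[xi < 0.5])) / mean(env[xi < 0.5]), 0.05)
  expect_gt(max(env[xi > 0.7]), 1.05 * mean(env[xi < 0.5]))
})

test_that("wall shear equals the wall gradient of the velocity profile", {
  set.seed(11)
  q <- 4e-4 + 2e-4 * sin(2 * pi * (0:239) / 240)
  h <- flow_harmonics(q, period = 1.5, n_harmonics = 10)
  r <- 0.02
  tt <- seq(0, 1.5, length.out = 9)
  eps <- 1e-4
  u <- velocity_profile(h, r, c(1 - 2 * eps, 1 - eps, 1), tt, blood)
  dudr <- (3 * u[3, ] - 4 * u[2, ] + u[1, ]) / (2 * eps * r)
  expect_equal(wall_shear(h, r, tt, blood), blood$viscosity * dudr,
    tolerance = 1e-4
  )
})

test_that("flat-profile momentum flux is the algebraic identity Q^2/A", {
  expect_equal(flat_momentum_flux(3e-4, 2e-4), 9e-8 / 2e-4)
  # and the Womersley integral recovers it in the steady limit
  h <- structure(
    list(q_mean = 2e-4, qn = complex(0), omega = 2 * pi / 1.5, period = 1.5),
    class = "flow_harmonics"
  )
  r <- 0.01
  psi <- momentum_flux_integral(h, r, t = 0, blood = blood)
  # Poiseuille profile carries 4/3 of the flat-profile momentum flux
  expect_equal(psi, 4 / 3 * flat_momentum_flux(2e-4, pi * r^2), tolerance = 1e-9)
})

test_that("three quarters of the packaged segments are in the oscillatory regime", {
  sim_alpha <- local({
    seg <- equine_segment_table()
    r_mid <- (seg$proximal_diameter_mm + seg$distal_diameter_mm) / 4 / 1000
    womersley_number(r_mid, 40 / 60, blood)
  })
  expect_equal(mean(sim_alpha > 3), 0.75, tolerance = 0.01)
})
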