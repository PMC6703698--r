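test_that("wave power splits exactly into forward and backward components", {
  # constructed pure forward wave: dP = Zc dQ sample by sample
  wf <- make_synthetic_waveforms("forward_only", zc = 0.01)
  wpa <- wave_power(wf$p, wf$q, wf$zc)
  expect_equal(wpa$dpi_minus, rep(0, nrow(wpa)))
  expect_equal(wpa$dpi_plus, wpa$dpi)
  # mirrored backward wave
  wpa_b <- wave_power(wf$p, -wf$q, wf$zc)
  expect_equal(wpa_b$dpi_plus, rep(0, nrow(wpa_b)))
  # random series: the sum identity is algebraic
  set.seed(42)
  p <- cumsum(rnorm(200))
  q <- cumsum(rnorm(200))
  wpa_r <- wave_power(p, q, 0.05)
  expect_equal(wpa_r$dpi_plus + wpa_r$dpi_minus, wpa_r$dpi, tolerance = 1e-12)
  expect_true(all(wpa_r$dpi_plus >= 0))
  expect_true(all(wpa_r$dpi_minus <= 0))
  expect_error(wave_power(p, q[-1], 0.05), "time grid")
})

test_that("wave foot detection is shift-equivariant", {
  wf <- make_synthetic_waveforms("shifted_pair", delay = 0.04, n_samples = 1500)
  t1 <- wave_foot(wf$p1, wf$time)
  t2 <- wave_foot(wf$p2, wf$time)
  dt <- wf$time[2] - wf$time[1]
  d <- (t2 - t1) %% wf$period
  expect_lt(min(abs(d - 0.04), abs(d - 0.04 - wf$period)), 3 * dt)
})

test_that("wave foot lands at the maximal-curvature point of a tanh upstroke", {
  period <- 1.5
  tt <- seq(0, period, length.out = 1501)[-1501]
  t0 <- 0.6
  w <- 0.05
  # periodic beat: tanh upstroke at t0, tanh return stroke late in the cycle
  p <- 50 + 30 * (tanh((tt - t0) / w) + 1) - 30 * (tanh((tt - 1.35) / 0.03) + 1)
  # second derivative of tanh(x) peaks at x = -atanh(1/sqrt(3)) * w + t0
  t_theory <- t0 - w * atanh(1 / sqrt(3))
  expect_lt(abs(wave_foot(p, tt) - t_theory), 0.005)
})

test_that("wave foot tolerates measurement noise", {
  # steep periodic beat: the foot is a sharp curvature maximum, as in a real
  # systolic upstroke
  tt <- seq(0, 1.5, length.out = 1501)[-1501]
  dt <- tt[2] - tt[1]
  p <- 50 + 30 * (tanh((tt - 0.6) / 0.05) + 1) -
    30 * (tanh((tt - 1.35) / 0.03) + 1)
  # with measurement noise the smoothing window is widened to match the
  # signal-to-noise ratio (it is an explicit parameter of the detector)
  w <- 0.06
  clean <- wave_foot(p, tt, window = w)
  pp <- max(p) - min(p)
  set.seed(3)
  err <- replicate(100, {
    noisy <- p + rnorm(length(p), 0, 0.01 * pp)
    d <- abs(wave_foot(noisy, tt, window = w) - clean)
    min(d, 1.5 - d)
  })
  expect_lt(stats::quantile(err, 0.95), 8 * dt)
  expect_lt(stats::median(err), 3 * dt)
})

test_that("foot-to-foot PWV recovers known speeds", {
  # two probes, 0.5 m apart, 0.1 s delay
  period <- 1.5
  tt <- seq(0, period, length.out = 1500 + 1)[-(1500 + 1)]
  pulse <- function(t) {
    80 + 40 * exp(-0.5 * (((t %% period) / period - 0.25) / 0.06)^2)
  }
  probes <- list(pulse(tt), pulse(tt - 0.1))
  expect_equal(
    pwv_foot_to_foot(probes, tt, distance_mm = c(0, 500)),
    5, tolerance = 0.02
  )
  # regression over several probes with jittered feet
  set.seed(5)
  speed <- 6.5
  d <- seq(0, 800, by = 100)
  probes <- lapply(d, function(x) pulse(tt - x / 1000 / speed))
  fit <- pwv_foot_to_foot(probes, tt, distance_mm = d)
  expect_equal(fit, speed, tolerance = 0.03)
  expect_error(
    pwv_foot_to_foot(list(pulse(tt), pulse(tt)), tt, c(0, 100)),
    "degenerate"
  )
})

test_that("reflection distance is half the round-trip product", {
  expect_equal(reflection_distance(0, 5), 0)
  expect_equal(reflection_distance(0.1, 5), 0.25)
  expect_equal(reflection_distance(0.2, 5), 2 * reflection_distance(0.1, 5))
  expect_equal(reflection_distance(0.1, 10), 2 * reflection_distance(0.1, 5))
})

test_that("ensemble averaging is idempotent and shrinks noise as 1/sqrt(n)", {
  wf <- make_synthetic_waveforms("noisy_beats", n_beats = 50, seed = 1)
  # identical clean beats average to one beat
  avg_clean <- ensemble_average(wf$clean, wf$time, wf$triggers)
  one_beat <- wf$clean[wf$time < wf$period]
  grid <- seq(0, wf$period, length.out = 200)
  expect_equal(
    avg_clean$mean,
    stats::approx(wf$time[wf$time < wf$period], one_beat, grid, rule = 2)$y,
    tolerance = 1e-6
  )
  expect_equal(attr(avg_clean, "n_beats"), 50)
  # noise suppression close to 1/sqrt(50)
  avg_noisy <- ensemble_average(wf$noisy, wf$time, wf$triggers)
  rms_after <- sqrt(mean((avg_noisy$mean - avg_clean$mean)^2))
  rms_before <- sqrt(mean((wf$noisy - wf$clean)^2))
  expect_equal(rms_after / rms_before, 1 / sqrt(50), tolerance = 0.35)
  expect_error(ensemble_average(wf$noisy, wf$time, wf$triggers[1]), "2 triggers")
})

test_that("summary identities hold on the packaged run", {
  sim <- equine_sim_cached(gravity = FALSE)
  g <- glance(sim)
  expect_equal(g$pulse_pressure_mmHg, g$systolic_mmHg - g$diastolic_mmHg)
  # CO * TVR = MAP by construction, to round-off
  expect_equal(g$co_l_min * 1000 / 60 * g$tvr_mmHg_s_ml, g$map_mmHg,
    tolerance = 1e-12
  )
  hs <- hemodynamic_summary(sim)
  expect_equal(sum(hs$regional_flow$share_pct), 100, tolerance = 1e-9)
})

test_that("constant waveforms give degenerate summary values", {
  sim <- equine_sim_cached(gravity = FALSE)
  wf <- probe_waveform(sim, "1", 0)
  p0 <- rep(100, length(wf$time))
  q0 <- rep(550, length(wf$time))
  expect_equal(max(p0) - min(p0), 0)
  wpa <- wave_power(p0, q0, 0.01)
  expect_true(all(wpa$dpi == 0))
})
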