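# Solver physics on analytically tractable fixtures.

test_that("closed inlet with blocked terminals stays at equilibrium", {
  net <- toy_network("single_tube",
    length_mm = 400, diameter_mm = 30,
    distensibility = 5, terminal_load = "blocked"
  )
  quiet_heart <- elastance_heart(emin = 1e-6, emax = 2e-6, p_end_diastolic = 1e-5)
  sim <- simulate_hemodynamics(net,
    heart = quiet_heart,
    config = solver_config(n_cycles = 1, initial_q = 0), quiet = TRUE
  )
  interior <- which(!sim$nodes$is_terminal_node)
  # the "blocked" terminal is a 1e6-fold resistance, so the only motion is
  # its physical leak (P/RT ~ 2e-3 ml/s); the interior stays at the initial
  # state to that scale
  leak <- 100 / (sim$network$terminals$R1 + sim$network$terminals$R2)
  expect_lt(max(abs(sim$q[interior, ])), 2 * leak)
  expect_lt(max(abs(sim$p[interior, ] - 100)), 5e-3)
})

test_that("constant inflow settles to the steady Windkessel pressure", {
  net <- toy_network("single_tube",
    length_mm = 300, diameter_mm = 10,
    distensibility = 3, terminal_load = "windkessel"
  )
  rt <- net$terminals$R1 + net$terminals$R2
  sim <- simulate_hemodynamics(net,
    config = solver_config(n_cycles = 6),
    inflow = function(t) rep(10, length(t)), quiet = TRUE
  )
  p_term <- sim$p[nrow(sim$p), ]
  expect_equal(mean(tail(p_term, 50)), 10 * rt, tolerance = 1e-4)
  # flow is uniform along the tube at steady state
  expect_equal(mean(tail(sim$q[1, ], 50)), 10, tolerance = 1e-4)
})

test_that("step inflow relaxes with the R2*CT Windkessel time constant", {
  net <- toy_network("single_tube",
    length_mm = 100, diameter_mm = 10,
    distensibility = 0.3, terminal_load = "windkessel"
  )
  # stiff short tube so the Windkessel dominates the compliance; CT set
  # explicitly so tube storage is negligible against it
  net$terminals$CT <- 0.05
  tp <- net$terminals
  tau_theory <- tp$R2 * tp$CT
  q0 <- 5
  q1 <- 15
  step_fun <- function(t) ifelse(t < 0.25, q0, q1)
  sim <- simulate_hemodynamics(net,
    config = solver_config(
      n_cycles = 1, initial_p = q0 * (tp$R1 + tp$R2), initial_q = q0
    ),
    inflow = step_fun, quiet = TRUE
  )
  p_term <- sim$p[nrow(sim$p), ]
  t_all <- sim$time
  sel <- t_all > 0.3 & t_all < 0.3 + 2 * tau_theory
  # exponential approach: fit log(P_inf - P) against t
  p_inf <- q1 * (tp$R1 + tp$R2)
  fit <- stats::lm(log(p_inf - p_term[sel]) ~ t_all[sel])
  tau_fit <- -1 / unname(stats::coef(fit)[2])
  expect_equal(tau_fit, tau_theory, tolerance = 0.05)
})

test_that("high-frequency input impedance of the Windkessel approaches R1", {
  net <- toy_network("single_tube",
    length_mm = 100, diameter_mm = 10,
    distensibility = 3, terminal_load = "windkessel"
  )
  tp <- net$terminals
  f_hi <- 40  # Hz: 1/(2 pi f) well below R2*CT
  q0 <- 10
  sim <- simulate_hemodynamics(net,
    config = solver_config(
      n_cycles = 3, dt = 2.5e-4,
      initial_p = q0 * (tp$R1 + tp$R2), initial_q = q0
    ),
    inflow = function(t) q0 + 2 * sin(2 * pi * f_hi * t), quiet = TRUE
  )
  n_steps <- length(sim$time) - 1
  g <- nrow(sim$p)  # terminal node
  p_osc <- sim$p[g, 1:n_steps] - mean(sim$p[g, 1:n_steps])
  q_osc <- sim$q[g, 1:n_steps] - mean(sim$q[g, 1:n_steps])
  k <- f_hi * 1.5 + 1  # bin of the driving frequency over one cycle record
  z_hat <- stats::fft(p_osc)[k] / stats::fft(q_osc)[k]
  expect_equal(Mod(z_hat), tp$R1, tolerance = 0.15)
})

test_that("small pulses travel at the analytic wave speed", {
  net <- toy_network("single_tube",
    length_mm = 1000, diameter_mm = 20,
    distensibility = 4, terminal_load = "windkessel"
  )
  rt <- net$terminals$R1 + net$terminals$R2
  q0 <- 100 / rt  # base flow so the tube sits at 100 mmHg
  pulse <- function(t) q0 + 5 * exp(-0.5 * ((t - 0.05) / 0.008)^2)
  sim <- simulate_hemodynamics(net,
    config = solver_config(
      n_cycles = 2, dx_max = 0.005, dt = 2.5e-4,
      initial_p = 100, initial_q = q0
    ),
    inflow = pulse, quiet = TRUE
  )
  n1 <- which.min(abs(sim$nodes$position_mm - 200))
  n2 <- which.min(abs(sim$nodes$position_mm - 800))
  w <- sim$time > 0.02 & sim$time < 0.4
  t1 <- sim$time[w][which.max(sim$p[n1, w])]
  t2 <- sim$time[w][which.max(sim$p[n2, w])]
  c_meas <- 0.6 / (t2 - t1)
  # forward characteristic speed: local wave speed plus advection by the
  # base flow (u0 = q0 / A)
  u0 <- q0 * 1e-6 / (pi / 4 * 0.02^2)
  c_theory <- local_pwv(100, 1, 4e-3) + u0
  expect_equal(c_meas, c_theory, tolerance = 0.02)
})

test_that("junctions conserve mass exactly and split symmetric daughters evenly", {
  net <- toy_network("symmetric_bifurcation", terminal_load = "windkessel")
  sim <- simulate_hemodynamics(net,
    config = solver_config(n_cycles = 2),
    inflow = function(t) 20 + 10 * sin(2 * pi * t / 1.5), quiet = TRUE
  )
  off <- sim$mesh$node_offset
  nn <- sim$mesh$n_nodes
  q_parent_out <- sim$q[off[1] + nn[1], ]
  q_d1 <- sim$q[off[2] + 1, ]
  q_d2 <- sim$q[off[3] + 1, ]
  expect_lt(max(abs(q_parent_out - q_d1 - q_d2)), 1e-8)
  expect_equal(q_d1, q_d2, tolerance = 1e-10)
  # pressure continuity at the junction
  p_parent_out <- sim$p[off[1] + nn[1], ]
  expect_lt(max(abs(p_parent_out - sim$p[off[2] + 1, ])), 1e-8)
})

test_that("asymmetric downstream loads split flow by inverse input impedance", {
  # two identical daughters with different terminal resistances; in the
  # steady (zero-frequency) limit the split equals the conductance ratio
  tab <- toy_network("symmetric_bifurcation", terminal_load = "windkessel")$segments
  net <- arterial_network(tab)
  term <- net$segments[net$segments$is_terminal, ]
  zc <- characteristic_impedance(
    term$distal_diameter_mm[1],
    distensibility_ref = term$distensibility_1e3_mmHg[1]
  )
  net$terminals <- tibble::tibble(
    terminal_id = term$segment_id, region = term$region,
    RT = c(2, 4), R1 = c(zc, zc), R2 = c(2, 4) - zc, CT = c(0.1, 0.05)
  )
  sim <- simulate_hemodynamics(net,
    config = solver_config(n_cycles = 6),
    inflow = function(t) rep(30, length(t)), quiet = TRUE
  )
  off <- sim$mesh$node_offset
  q1 <- mean(tail(sim$q[off[2] + 1, ], 50))
  q2 <- mean(tail(sim$q[off[3] + 1, ], 50))
  # input impedance = tube series resistance + RT; tube part is small
  expect_equal(q1 / q2, 2, tolerance = 0.02)
})

test_that("zero angles make the gravity flag a no-op, bitwise", {
  tab <- toy_network("three_generation_tree", terminal_load = "windkessel")$segments
  tab$angle_1d <- 0
  net <- derive_terminal_parameters(arterial_network(tab))
  cfg <- solver_config(n_cycles = 2)
  inflow <- function(t) 20 + 10 * sin(2 * pi * t / 1.5)
  sim0 <- simulate_hemodynamics(net, config = cfg, inflow = inflow, quiet = TRUE)
  sim1 <- simulate_hemodynamics(net,
    config = cfg, inflow = inflow,
    gravity = TRUE, quiet = TRUE
  )
  expect_identical(sim0$p, sim1$p)
  expect_identical(sim0$q, sim1$q)
})

test_that("identical inputs give identical outputs (determinism)", {
  net <- toy_network("single_tube", terminal_load = "windkessel")
  cfg <- solver_config(n_cycles = 2)
  s1 <- simulate_hemodynamics(net, config = cfg, quiet = TRUE)
  s2 <- simulate_hemodynamics(net, config = cfg, quiet = TRUE)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$q, s2$q)
})
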