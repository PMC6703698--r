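#' Run the invariant suite on a simulation result
#'
#' Checks the physical and numerical invariants of a completed run:
#' positivity of areas and terminal pressures, per-step mass conservation at
#' every junction, global volume balance over the final cycle (inlet volume
#' vs terminal outflow plus network storage), cycle-to-cycle periodicity,
#' junction reflection coefficients, and the wave-power identity
#' `dpi_plus + dpi_minus = dP dQ` at the root.
#'
#' @param sim A `hemo_sim` result.
#' @param tol_mass Junction flow-conservation tolerance, ml/s.
#' @param tol_balance Relative global volume-balance tolerance.
#' @param tol_periodicity Relative waveform-change tolerance between the
#'   final two cycles.
#' @param max_gamma Junction reflection-coefficient bound.
#' @return A tibble with one row per check: `check`, `value`, `bound`,
#'   `pass`.
#' @export
validate_simulation <- function(sim, tol_mass = 1e-3, tol_balance = 5e-3,
                                tol_periodicity = 5e-3, max_gamma = 0.2) {
  n_steps <- length(sim$time) - 1
  sel <- seq_len(n_steps)
  mesh <- sim$mesh
  seg <- sim$network$segments

  checks <- list()
  add <- function(check, value, bound, pass = value <= bound) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, value = value, bound = bound, pass = pass
    )
  }

  add("area_min_mm2", -min(sim$a), 0, min(sim$a) > 0)
  term_nodes <- which(sim$nodes$is_terminal_node)
  add(
    "terminal_pressure_min_mmHg", -min(sim$p[term_nodes, ]), 0,
    min(sim$p[term_nodes, ]) > 0
  )

  # junction mass conservation at every recorded step
  idx <- stats::setNames(seq_len(nrow(seg)), seg$segment_id)
  worst <- 0
  for (p in names(sim$network$children)) {
    ds <- sim$network$children[[p]]
    if (length(ds) == 0) next
    s <- idx[[p]]
    g_par <- mesh$node_offset[s] + mesh$n_nodes[s]
    g_dau <- mesh$node_offset[idx[ds]] + 1
    qsum <- colSums(sim$q[g_dau, , drop = FALSE])
    worst <- max(worst, max(abs(sim$q[g_par, ] - qsum)))
  }
  add("junction_mass_error_ml_s", worst, tol_mass)

  # global volume balance over the final cycle
  dt <- sim$dt
  v_in <- sum(sim$q[1, sel]) * dt
  v_out <- sum(sim$q[term_nodes, sel]) * dt
  # network volume change: integral of A over segments at first vs last sample
  dv <- 0
  for (s in seq_len(nrow(seg))) {
    gi <- mesh$node_offset[s] + seq_len(mesh$n_nodes[s])
    a1 <- sim$a[gi, 1] * 1e-6
    a2 <- sim$a[gi, n_steps + 1] * 1e-6
    h <- mesh$h[s]
    dv <- dv + sum((a2 - a1) * h) - (a2[1] - a1[1]) * h / 2 -
      (a2[length(gi)] - a1[length(gi)]) * h / 2
  }
  dv <- dv * 1e6  # ml
  balance_err <- abs(v_in - v_out - dv) / max(v_in, 1e-9)
  add("global_volume_balance_rel", balance_err, tol_balance)

  add(
    "cycle_periodicity_rel",
    sim$cycles$waveform_change[nrow(sim$cycles)], tol_periodicity
  )

  gam <- junction_reflections(sim$network)
  add("max_junction_gamma", max(abs(gam$gamma)), max_gamma)

  wpa <- probe_wave_power(sim, sim$network$root_id, 0)
  wf <- probe_waveform(sim, sim$network$root_id, 0)
  to_mw <- MMHG_PA * 1e-6 * 1000
  ident <- max(abs(wpa$dpi_plus + wpa$dpi_minus - diff(wf$p) * diff(wf$q) * to_mw))
  add("wave_power_identity_mW", ident, 1e-9 * max(abs(wpa$dpi), 1))

  dplyr::bind_rows(checks)
}
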