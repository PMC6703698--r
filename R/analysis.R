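#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' One-row summary of a simulation
#'
#' Global haemodynamics of the converged final cycle: cardiac output (mean
#' aortic-root flow times 60), stroke volume and ejection fraction from the
#' ventricular volume ledger, aortic-root systolic/diastolic/mean/pulse
#' pressure, and total vascular resistance `TVR = MAP / CO` (which exceeds
#' the parallel combination of the terminal resistances because the vessels'
#' series resistances contribute).
#'
#' @param x A `hemo_sim` result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hemo_sim <- function(x, ...) {
  n_steps <- length(x$time) - 1
  root <- 1  # proximal node of the root segment
  p_root <- x$p[root, ]
  q_root <- x$q[root, ]
  co_ml_s <- mean(q_root[seq_len(n_steps)])
  cyc <- x$cycles[nrow(x$cycles), ]
  map <- mean(p_root[seq_len(n_steps)])
  tibble::tibble(
    co_l_min = co_ml_s * 60 / 1000,
    sv_ml = cyc$sv,
    ef_pct = 100 * cyc$ef,
    edv_ml = cyc$edv,
    esv_ml = cyc$esv,
    systolic_mmHg = max(p_root),
    diastolic_mmHg = min(p_root),
    pulse_pressure_mmHg = max(p_root) - min(p_root),
    map_mmHg = map,
    tvr_mmHg_s_ml = map / co_ml_s,
    gravity = x$gravity,
    cycle_periodicity = cyc$waveform_change
  )
}

#' Per-node waveform summary of a simulation
#'
#' @param x A `hemo_sim` result.
#' @param ... Unused.
#' @return A tibble with one row per mesh node: pressure extrema and mean,
#'   pulse pressure, mean flow and peak velocity.
#' @export
tidy.hemo_sim <- function(x, ...) {
  n_steps <- length(x$time) - 1
  sel <- seq_len(n_steps)
  vel <- x$q / x$a  # m/s
  dplyr::mutate(
    x$nodes,
    p_systolic = apply(x$p, 1, max),
    p_diastolic = apply(x$p, 1, min),
    p_mean = rowMeans(x$p[, sel, drop = FALSE]),
    pulse_pressure = .data$p_systolic - .data$p_diastolic,
    q_mean = rowMeans(x$q[, sel, drop = FALSE]),
    velocity_peak = apply(vel, 1, max),
    velocity_mean = rowMeans(vel[, sel, drop = FALSE])
  )
}

#' Full haemodynamic summary of a simulation
#'
#' Global quantities (as [glance.hemo_sim()]), the regional distribution of
#' cardiac output over the terminal beds, and per-probe dimensionless numbers
#' (Womersley number, maximum wall shear stress, mean convective
#' acceleration, Reynolds number) at the canonical probe sites: proximal
#' aorta (segment 1), distal aorta (87), common carotid (49), median artery
#' (26) and external iliac artery (93).
#'
#' @param sim A `hemo_sim` result.
#' @param probes Named list of probe sites: `name = c(segment_id, position_mm)`.
#' @return A list of tibbles: `global`, `regional_flow`, `sites`.
#' @export
hemodynamic_summary <- function(sim,
                                probes = list(
                                  prox_aorta = c("1", 0),
                                  dist_aorta = c("87", 63),
                                  cca = c("49", 355),
                                  median = c("26", 145),
                                  ext_iliac = c("93", 115)
                                )) {
  n_steps <- length(sim$time) - 1
  sel <- seq_len(n_steps)
  global <- glance(sim)

  # regional flow distribution from terminal mean outflows
  term_nodes <- which(sim$nodes$is_terminal_node)
  q_term <- rowMeans(sim$q[term_nodes, sel, drop = FALSE])
  reg <- tibble::tibble(
    region = sim$nodes$region[term_nodes],
    q_mean = q_term
  )
  regional <- dplyr::summarise(
    dplyr::group_by(reg, .data$region),
    q_mean_ml_s = sum(.data$q_mean), .groups = "drop"
  )
  regional$share_pct <- 100 * regional$q_mean_ml_s / sum(regional$q_mean_ml_s)

  blood <- sim$network$blood
  hr_f <- sim$heart$hr / 60
  sites <- purrr::map_dfr(names(probes), function(nm) {
    pr <- probes[[nm]]
    wf <- probe_waveform(sim, pr[1], as.numeric(pr[2]))
    sel_node <- which(
      sim$nodes$segment_id == pr[1] &
        sim$nodes$position_mm == wf$position_mm[1]
    )[1]
    r_m <- sim$nodes$radius_ref_mm[sel_node] / 1000
    seg_row <- which(sim$network$segments$segment_id == pr[1])
    r_mid <- (sim$network$segments$proximal_diameter_mm[seg_row] +
      sim$network$segments$distal_diameter_mm[seg_row]) / 4 / 1000
    q_si <- wf$q * 1e-6
    h <- flow_harmonics(q_si[sel], sim$period, sim$config$n_harmonics)
    tau <- wall_shear(h, r_m, sim$time, blood)
    # mean convective acceleration d/dx(int u^2 dA) at the probe node
    conv <- probe_convective_mean(sim, pr[1], wf$position_mm[1])
    vbar <- mean(wf$velocity[sel])
    d_m <- 2 * r_m
    tibble::tibble(
      site = nm, segment_id = pr[1], position_mm = wf$position_mm[1],
      alpha = womersley_number(r_mid, hr_f, blood),
      tau_max_pa = max(abs(tau)),
      tau_max_signed_pa = tau[which.max(abs(tau))],
      conv_mean_m3_s2 = conv,
      reynolds = blood$density * abs(vbar) * d_m / blood$viscosity,
      velocity_peak_m_s = max(wf$velocity)
    )
  })

  list(global = global, regional_flow = regional, sites = sites)
}

# Cycle-mean of the convective-acceleration term d/dx(int u^2 dA) at a probe,
# from the final-cycle solution (Womersley profile for high-alpha segments,
# flat profile otherwise).
probe_convective_mean <- function(sim, segment_id, position_mm) {
  seg <- sim$network$segments
  s <- which(seg$segment_id == as.character(segment_id))
  gidx <- which(sim$mesh$seg_of_node == s)
  n <- length(gidx)
  n_steps <- length(sim$time) - 1
  sel <- seq_len(n_steps)
  blood <- sim$network$blood
  use_womersley <- sim$alpha_seg[s] > sim$config$alpha_threshold
  psi <- matrix(0, n, length(sel))
  for (i in seq_len(n)) {
    g <- gidx[i]
    q_si <- sim$q[g, sel] * 1e-6
    if (use_womersley) {
      h <- flow_harmonics(q_si, sim$period, sim$config$n_harmonics)
      psi[i, ] <- momentum_flux_integral(
        h, sim$mesh$radius_ref[g], sim$time[sel], blood,
        n_radial = sim$config$n_radial
      )
    } else {
      psi[i, ] <- q_si^2 / (sim$a[g, sel] * 1e-6)
    }
  }
  hh <- sim$mesh$h[s]
  node_x <- sim$nodes$position_mm[gidx]
  i0 <- which.min(abs(node_x - position_mm))
  dpsi <- if (i0 == 1) {
    (-3 * psi[1, ] + 4 * psi[2, ] - psi[3, ]) / (2 * hh)
  } else if (i0 == n) {
    (3 * psi[n, ] - 4 * psi[n - 1, ] + psi[n - 2, ]) / (2 * hh)
  } else {
    (psi[i0 + 1, ] - psi[i0 - 1, ]) / (2 * hh)
  }
  mean(dpsi)
}

#' Forward/backward wave power decomposition
#'
#' Splits the wave power `dpi = dP * dQ` (per sample) into forward and
#' backward components using the local characteristic impedance:
#' `dpi_plus = (dP + Zc dQ)^2 / (4 Zc)` and
#' `dpi_minus = -(dP - Zc dQ)^2 / (4 Zc)`, so that
#' `dpi_plus + dpi_minus = dpi` identically.
#'
#' @param p Pressure series, mmHg.
#' @param q Flow series, ml/s (same grid as `p`).
#' @param zc Local characteristic impedance, mmHg.s/ml.
#' @param time Optional time grid, s.
#' @return A tibble with `dpi`, `dpi_plus`, `dpi_minus` (mW) per sample
#'   interval (length `length(p) - 1`).
#' @export
wave_power <- function(p, q, zc, time = NULL) {
  if (length(p) != length(q)) stop("p and q must share a time grid")
  stopifnot(zc > 0)
  dp <- diff(p)
  dq <- diff(q)
  dpi_plus <- (dp + zc * dq)^2 / (4 * zc)
  dpi_minus <- -(dp - zc * dq)^2 / (4 * zc)
  # mmHg * ml/s = 133.322e-6 W = 0.133322 mW
  to_mw <- MMHG_PA * 1e-6 * 1000
  out <- tibble::tibble(
    dpi = (dp * dq) * to_mw,
    dpi_plus = dpi_plus * to_mw,
    dpi_minus = dpi_minus * to_mw
  )
  if (!is.null(time)) out$time <- time[-length(time)]
  out
}

#' Wave power decomposition at a probe site
#'
#' @param sim A `hemo_sim` result.
#' @param segment_id,position_mm Probe location.
#' @return Tibble from [wave_power()] with a `time` column.
#' @export
probe_wave_power <- function(sim, segment_id, position_mm = 0) {
  wf <- probe_waveform(sim, segment_id, position_mm)
  seg <- sim$network$segments
  s <- which(seg$segment_id == as.character(segment_id))
  node <- which(
    sim$nodes$segment_id == as.character(segment_id) &
      sim$nodes$position_mm == wf$position_mm[1]
  )[1]
  a_ref <- pi * (sim$nodes$radius_ref_mm[node] / 1000)^2
  zc <- .zc_of_area(a_ref, seg$delta_mmHg[s], sim$network$law, sim$network$blood)
  wave_power(wf$p, wf$q, zc, time = wf$time)
}

#' Foot of a pressure wave
#'
#' Detects the foot of the systolic upstroke as the time of the peak of the
#' second time-derivative of pressure within the upstroke window.  The
#' derivative is taken with a Savitzky-Golay local cubic fit (default window
#' 25 ms) so that sampling noise does not dominate the second difference.
#' The series is treated as one full cycle of a periodic signal.
#'
#' @param p Pressure series over exactly one cycle, mmHg.
#' @param time Time grid, s.
#' @param window Smoothing window for the local polynomial derivative, s.
#' @return Foot time, s.
#' @export
wave_foot <- function(p, time, window = 0.025) {
  n <- length(p)
  if (n < 7) stop("pressure series too short")
  dt <- time[2] - time[1]
  half <- max(2, round(window / 2 / dt))
  # Savitzky-Golay local cubic: smoothed value (for the upstroke window) and
  # second derivative (for the foot); edge-replicated padding
  x <- (-half:half) * dt
  xm <- cbind(1, x, x^2, x^3)
  coefs <- solve(crossprod(xm), t(xm))
  proj0 <- coefs[1, ]
  proj2 <- coefs[3, ] * 2
  pad <- c(p[(n - half + 1):n], p, p[1:half])  # periodic continuation
  sm <- as.numeric(stats::filter(pad, rev(proj0), sides = 2))[half + seq_len(n)]
  # second derivative of the pre-smoothed series: the cascade halves the
  # noise gain of the bare second-difference at minor cost in peak width
  pad_sm <- c(sm[(n - half + 1):n], sm, sm[1:half])
  d2 <- as.numeric(stats::filter(pad_sm, rev(proj2), sides = 2))[half + seq_len(n)]
  # upstroke window: from the (smoothed) pressure minimum to the following
  # maximum, wrapping around the cycle if needed
  i_min <- which.min(sm)
  i_max <- which.max(sm)
  idx <- if (i_min <= i_max) i_min:i_max else c(i_min:n, 1:i_max)
  if (length(idx) < 3) stop("no systolic upstroke found")
  foot_idx <- idx[which.max(d2[idx])]
  time[foot_idx]
}

#' Foot-to-foot pulse wave velocity
#'
#' Transit-time PWV from pressure waveforms at probes of known arc distance:
#' each wave foot is located with [wave_foot()] and PWV is the slope of the
#' regression of distance on foot delay (emulating a stepwise catheter
#' pull-back).
#'
#' @param probes A data frame with columns `distance_mm` and a list-column
#'   `p` of pressure series (shared time grid), or a list of such series with
#'   `distance_mm` given separately.
#' @param time Shared time grid, s.
#' @param distance_mm Probe arc distances, mm (when `probes` is a plain list).
#' @return PWV in m/s.
#' @export
pwv_foot_to_foot <- function(probes, time, distance_mm = NULL) {
  if (is.data.frame(probes)) {
    distance_mm <- probes$distance_mm
    plist <- probes$p
  } else {
    plist <- probes
  }
  if (length(plist) < 2) stop("need at least two probes")
  feet <- vapply(plist, wave_foot, numeric(1), time = time)
  period <- max(time) - min(time)
  # unwrap framing: feet must be non-decreasing along the path
  for (i in seq_along(feet)[-1]) {
    while (feet[i] < feet[i - 1] - period / 2) feet[i] <- feet[i] + period
  }
  if (stats::sd(feet) == 0) stop("all wave feet coincide; delays are degenerate")
  fit <- stats::lm(I(distance_mm / 1000) ~ feet)
  unname(stats::coef(fit)[2])
}

#' Distance to a reflection site
#'
#' A wave reflected at distance `L` returns after travelling `2 L`, so
#' `L = dt * pwv / 2` for transit-time difference `dt` and local theoretical
#' pulse wave velocity `pwv`.
#'
#' @param dt Time between a wave and its reflection, s.
#' @param pwv Local pulse wave velocity, m/s.
#' @return Distance in m.
#' @examples
#' reflection_distance(0.1, 5)  # 0.25 m
#' @export
reflection_distance <- function(dt, pwv) {
  stopifnot(all(dt >= 0), all(pwv > 0))
  dt * pwv / 2
}

#' Ensemble-average beats
#'
#' Aligns beats at trigger times (emulating R-wave gating), resamples each
#' beat to a common grid and returns the pointwise mean waveform.
#'
#' @param x Signal samples.
#' @param time Time grid, s.
#' @param triggers Trigger times (beat onsets), s; at least 2, defining at
#'   least one complete beat per consecutive pair.
#' @param n_out Samples in the averaged beat.
#' @return A tibble with `time` (beat-relative) and `mean` waveform plus the
#'   number of beats averaged in attribute `n_beats`.
#' @export
ensemble_average <- function(x, time, triggers, n_out = 200) {
  triggers <- sort(triggers)
  if (length(triggers) < 2) stop("need at least 2 triggers (one complete beat)")
  beats <- list()
  for (i in seq_len(length(triggers) - 1)) {
    sel <- time >= triggers[i] & time < triggers[i + 1]
    if (sum(sel) < 4) next
    tt <- time[sel] - triggers[i]
    dur <- triggers[i + 1] - triggers[i]
    grid <- seq(0, dur, length.out = n_out)
    beats[[length(beats) + 1]] <- stats::approx(tt, x[sel], xout = grid, rule = 2)$y
  }
  if (length(beats) < 1) stop("fewer than one complete beat in the record")
  m <- do.call(rbind, beats)
  out <- tibble::tibble(
    time = seq(0, 1, length.out = n_out) * mean(diff(triggers)),
    mean = colMeans(m)
  )
  attr(out, "n_beats") <- length(beats)
  out
}

#' Plot pressure and flow waveforms of a simulation
#'
#' @param object A `hemo_sim` result.
#' @param probes Named list of probe sites (`name = c(segment_id, position_mm)`).
#' @param ... Unused.
#' @return A ggplot object (pressure and flow per probe over the final cycle).
#' @export
autoplot.hemo_sim <- function(object,
                              probes = list(
                                prox_aorta = c("1", 0),
                                cca = c("49", 355),
                                median = c("26", 145),
                                ext_iliac = c("93", 115)
                              ), ...) {
  df <- purrr::map_dfr(names(probes), function(nm) {
    pr <- probes[[nm]]
    wf <- probe_waveform(object, pr[1], as.numeric(pr[2]))
    wf$site <- nm
    wf
  })
  long <- tidyr::pivot_longer(
    df[, c("time", "site", "p", "q")],
    cols = c("p", "q"), names_to = "signal", values_to = "value"
  )
  long$signal <- factor(long$signal, c("p", "q"), c("pressure (mmHg)", "flow (ml/s)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value, colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time in cycle (s)", y = NULL, colour = "site") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wave power decomposition
#'
#' @param wpa A tibble from [wave_power()] (with a `time` column).
#' @return A ggplot object.
#' @export
plot_wave_power <- function(wpa) {
  long <- tidyr::pivot_longer(wpa, c("dpi_plus", "dpi_minus", "dpi"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value, colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time in cycle (s)", y = "wave power (mW)") +
    ggplot2::theme_minimal()
}
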