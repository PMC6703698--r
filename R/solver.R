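#' Solver configuration
#'
#' Numerical settings for the 1D network solver.  Defaults: second-order
#' Crank-Nicolson time integration with `dt` = 1 ms, node spacing at most
#' 10 mm with at least 3 nodes per segment, 8 cardiac cycles from a uniform
#' initial state of 100 mmHg and 1 ml/s, Newton tolerance 1e-8 (relative,
#' on the update norm) with at most 20 iterations, 20 flow harmonics and 64
#' radial Gauss points for the Witzig-Womersley friction and convective
#' corrections.
#'
#' @param dt Time step, s.
#' @param dx_max Maximum node spacing, m.
#' @param min_nodes Minimum nodes per segment (short stubs are resolved
#'   with at least this many nodes; fewer than 5 makes the one-sided end
#'   stencils of very short tapered stubs fragile).
#' @param n_cycles Number of cardiac cycles.
#' @param newton_tol Relative Newton tolerance.
#' @param max_newton_iter Maximum Newton iterations per step.
#' @param theta Implicitness parameter of the one-step theta scheme;
#'   0.5 is Crank-Nicolson, the default 0.55 adds a small high-frequency
#'   damping that suppresses neutrally stable grid modes while keeping the
#'   scheme effectively second order at the step sizes used.
#' @param n_harmonics Flow harmonics for the oscillatory-flow theory.
#' @param n_radial Radial Gauss points for profile integrals.
#' @param initial_p Initial pressure, mmHg.
#' @param initial_q Initial flow, ml/s.
#' @param alpha_threshold Womersley number above which the full oscillatory
#'   theory is used (flat-profile closure below).
#' @param dissipation Coefficient of the scale-selective (4th-difference)
#'   artificial dissipation on flow; damps the odd-even grid mode of the
#'   collocated central scheme without affecting resolved wavelengths.
#' @param conv_deviation Logical: include the (small) difference between the
#'   Womersley-profile and flat-profile momentum-flux terms as a frozen
#'   source?  The flat-profile closure and the Womersley friction are always
#'   active; at Womersley numbers above 3 the profile is nearly flat, so
#'   this deviation is a second-order correction.  Off by default because
#'   its cycle-to-cycle feedback can destabilise short tapered segments.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-3, dx_max = 0.01, min_nodes = 5, n_cycles = 8,
                          newton_tol = 1e-8, max_newton_iter = 20, theta = 0.55,
                          n_harmonics = 20, n_radial = 64,
                          initial_p = 100, initial_q = 1,
                          alpha_threshold = 3, dissipation = 0.01,
                          conv_deviation = FALSE) {
  stopifnot(dt > 0, dx_max > 0, min_nodes >= 3, n_cycles >= 1, theta > 0, theta <= 1)
  structure(
    list(
      dt = dt, dx_max = dx_max, min_nodes = min_nodes, n_cycles = n_cycles,
      newton_tol = newton_tol, max_newton_iter = max_newton_iter,
      theta = theta, n_harmonics = n_harmonics, n_radial = n_radial,
      initial_p = initial_p, initial_q = initial_q,
      alpha_threshold = alpha_threshold, dissipation = dissipation,
      conv_deviation = conv_deviation
    ),
    class = "solver_config"
  )
}

# Discretise the network into a node mesh; returns the list consumed by the
# C++ core plus node metadata used for post-processing.
build_mesh <- function(network, config, gravity = FALSE) {
  seg <- network$segments
  ns <- nrow(seg)
  idx <- stats::setNames(seq_len(ns), seg$segment_id)
  n_nodes_seg <- pmax(config$min_nodes, ceiling(seg$length_mm / 1000 / config$dx_max) + 1)
  offset <- cumsum(c(0, n_nodes_seg[-ns]))
  total <- sum(n_nodes_seg)

  area_ref <- numeric(total)
  radius_ref <- numeric(total)
  delta <- numeric(total)
  g_eff <- numeric(total)
  x_node <- numeric(total)
  seg_of_node <- integer(total)
  h <- numeric(ns)
  for (s in seq_len(ns)) {
    n <- n_nodes_seg[s]
    gidx <- offset[s] + seq_len(n)
    h[s] <- seg$length_mm[s] / 1000 / (n - 1)
    frac <- seq(0, 1, length.out = n)
    d <- seg$proximal_diameter_mm[s] + frac *
      (seg$distal_diameter_mm[s] - seg$proximal_diameter_mm[s])
    radius_ref[gidx] <- d / 2000
    area_ref[gidx] <- pi / 4 * (d / 1000)^2
    delta[gidx] <- seg$delta_mmHg[s] / MMHG_PA
    g_eff[gidx] <- if (gravity) network$blood$gravity * seg$cos_theta[s] else 0
    x_node[gidx] <- frac * seg$length_mm[s]
    seg_of_node[gidx] <- s
  }

  parent <- ifelse(is.na(seg$parent_id), -1L, idx[seg$parent_id] - 1L)
  kids <- lapply(seg$segment_id, function(id) {
    ch <- network$children[[id]]
    if (is.null(ch)) integer(0) else unname(idx[ch] - 1L)
  })
  child_ptr <- cumsum(c(0L, lengths(kids)))
  child_idx <- unlist(kids, use.names = FALSE)
  if (is.null(child_idx)) child_idx <- integer(0)

  # topological order: parents before children
  topo <- integer(0)
  frontier <- which(parent == -1L) - 1L
  while (length(frontier) > 0) {
    topo <- c(topo, frontier)
    frontier <- unlist(lapply(frontier, function(s) kids[[s + 1]]), use.names = FALSE)
  }

  term_index <- rep(-1L, ns)
  tp <- terminal_parameters(network)
  term_index[idx[tp$terminal_id]] <- seq_len(nrow(tp)) - 1L

  # fundamental Womersley number per segment at the mid-tapered radius
  f0 <- NULL  # filled by caller (depends on heart rate)

  list(
    node_offset = as.integer(offset), n_nodes = as.integer(n_nodes_seg),
    h = h, area_ref = area_ref, delta = delta, g_eff = g_eff,
    parent = as.integer(parent), child_ptr = as.integer(child_ptr),
    child_idx = as.integer(child_idx), terminal_index = term_index,
    topo_order = as.integer(topo),
    radius_ref = radius_ref, x_node = x_node, seg_of_node = seg_of_node,
    total_nodes = total, windkessel = tp
  )
}

# Witzig-Womersley refresh: from the previous cycle's nodal flows build the
# frozen friction and convective-acceleration source arrays for the segments
# with alpha above the threshold.
refresh_womersley_sources <- function(q_hist, a_hist, mesh, womersley_segs, blood,
                                      period, config, conv_deviation = TRUE) {
  n_steps <- ncol(q_hist) - 1
  n_nodes <- nrow(q_hist)
  k_harm <- config$n_harmonics
  omega <- 2 * pi / period
  t_grid <- (0:n_steps) * period / n_steps

  fric_src <- matrix(0, n_nodes, n_steps + 1)
  conv_src <- matrix(0, n_nodes, n_steps + 1)

  w_nodes <- which(mesh$seg_of_node %in% womersley_segs)
  if (length(w_nodes) == 0) {
    return(list(fric = fric_src, conv = conv_src))
  }

  qmat <- q_hist[w_nodes, seq_len(n_steps), drop = FALSE]
  coefs <- t(stats::mvfft(t(qmat))) / n_steps
  q_mean <- Re(coefs[, 1])
  qn <- 2 * coefs[, 1 + seq_len(k_harm), drop = FALSE]  # nodes x harmonics

  r <- mesh$radius_ref[w_nodes]
  a_ref <- mesh$area_ref[w_nodes]
  alpha <- outer(r, sqrt(blood$density * (seq_len(k_harm)) * omega / blood$viscosity))

  # ---- wall friction: tau(t) per node, then -(2 pi R / rho) tau ----
  shear_fac <- matrix(
    .womersley_shear_factor(as.vector(alpha)),
    nrow = length(w_nodes)
  )
  ctau <- (blood$viscosity / (pi * r^3)) * qn * shear_fac  # complex coef per harmonic
  e_full <- exp(1i * outer(seq_len(k_harm) * omega, t_grid))  # harmonics x times
  tau <- Re(ctau %*% e_full) - 4 * blood$viscosity * q_mean / (pi * r^3)
  # deviation from the implicit Poiseuille closure at the previous-cycle state
  fric_src[w_nodes, ] <- -(2 * pi * r / blood$density) * tau -
    8 * pi * (blood$viscosity / blood$density) * q_hist[w_nodes, ] / a_hist[w_nodes, ]

  # ---- convective acceleration: psi = int u^2 dA on a coarse periodic time
  #      grid, Fourier-interpolated to the solver grid ----
  m_coarse <- max(96, 4 * k_harm + 16)
  t_coarse <- (0:(m_coarse - 1)) * period / m_coarse
  e_coarse <- exp(1i * outer(seq_len(k_harm) * omega, t_coarse))
  gl <- gauss_legendre_01(config$n_radial)
  psi <- matrix(0, length(w_nodes), m_coarse)
  # profile factors per (node, harmonic, xi): batch the Bessel evaluations
  lam <- .lambda_of_alpha(as.vector(alpha))  # nodes*harm
  denom <- 1 - 2 * besselj01_complex(lam, scaled = TRUE)$j1 /
    (lam * besselj01_complex(lam, scaled = TRUE)$j0)
  j0_lam <- besselj01_complex(lam, scaled = TRUE)$j0
  nh <- length(lam)
  nxi <- length(gl$x)
  zfull <- lam %o% gl$x  # (nodes*harm) x xi
  j0_z <- matrix(besselj01_complex(as.vector(zfull), scaled = TRUE)$j0, nrow = nh)
  ratio <- (j0_z / j0_lam) * exp(abs(Im(lam)) * (matrix(gl$x, nh, nxi, byrow = TRUE) - 1))
  prof <- (1 - ratio) / denom  # (nodes*harm) x xi

  nnod <- length(w_nodes)
  # complex velocity coefficients c[node, harm, xi] = (qn/A) * prof
  cqa <- as.vector(qn / a_ref)  # node-major over (node, harm)
  cprof <- prof * cqa
  # reshape to (node*xi) x harm for one big multiply
  dim(cprof) <- c(nnod, k_harm, nxi)
  cprof <- aperm(cprof, c(1, 3, 2))
  dim(cprof) <- c(nnod * nxi, k_harm)
  u_osc <- Re(cprof %*% e_coarse)  # (node*xi) x times
  u_steady <- as.vector(outer(2 * q_mean / a_ref, (1 - gl$x^2)))
  u <- u_osc + u_steady
  dim(u) <- c(nnod, nxi, m_coarse)
  wq <- 2 * gl$w * gl$x
  for (m in seq_len(m_coarse)) {
    psi[, m] <- pi * mesh$radius_ref[w_nodes]^2 * (u[, , m]^2 %*% wq)
  }
  # Fourier interpolation of psi (periodic, band-limited) to the solver grid
  psi_hat <- t(stats::mvfft(t(psi))) / m_coarse
  kk <- 0:(m_coarse - 1)
  kk <- ifelse(kk <= m_coarse / 2, kk, kk - m_coarse)
  interp <- exp(1i * outer(kk * omega, t_grid))
  # halve the Nyquist coefficient (appears once, split symmetric)
  psi_hat[, m_coarse / 2 + 1] <- psi_hat[, m_coarse / 2 + 1] / 2
  interp2 <- rbind(interp, Conj(interp[m_coarse / 2 + 1, , drop = FALSE]))
  psi_hat2 <- cbind(psi_hat, psi_hat[, m_coarse / 2 + 1])
  psi_dense <- Re(psi_hat2 %*% interp2)

  # d(psi)/dx within each segment (2nd-order one-sided at the ends), minus
  # the upwind-differenced flat-profile flux at the previous-cycle state
  # (which the solver applies implicitly), leaving the deviation source.
  for (s in womersley_segs) {
    gidx <- which(mesh$seg_of_node == s)
    rows <- match(gidx, w_nodes)
    ps <- psi_dense[rows, , drop = FALSE]
    n <- length(gidx)
    hh <- mesh$h[s]
    d <- ps
    d[1, ] <- (-3 * ps[1, ] + 4 * ps[2, ] - ps[3, ]) / (2 * hh)
    d[n, ] <- (3 * ps[n, ] - 4 * ps[n - 1, ] + ps[n - 2, ]) / (2 * hh)
    if (n > 2) {
      d[2:(n - 1), ] <- (ps[3:n, , drop = FALSE] - ps[1:(n - 2), , drop = FALSE]) / (2 * hh)
    }
    pf <- q_hist[gidx, , drop = FALSE]^2 / a_hist[gidx, , drop = FALSE]
    df <- pf
    df[1, ] <- (pf[2, ] - pf[1, ]) / hh
    df[n, ] <- (pf[n, ] - pf[n - 1, ]) / hh
    if (n > 2) {
      for (i in 2:(n - 1)) {
        up <- q_hist[gidx[i], ] >= 0
        df[i, ] <- ifelse(up,
          (pf[i, ] - pf[i - 1, ]) / hh,
          (pf[i + 1, ] - pf[i, ]) / hh
        )
      }
    }
    conv_src[gidx, ] <- d - df
  }
  if (!conv_deviation) conv_src[] <- 0
  list(fric = fric_src, conv = conv_src)
}

#' Run the 1D pulse wave propagation simulation
#'
#' Solves the area-averaged continuity and momentum equations over the whole
#' network for `config$n_cycles` cardiac cycles: implicit second-order finite
#' differences in space and time, pressure/flow continuity at junctions,
#' three-element Windkessel terminal loads, and the four-phase elastance
#' ventricle at the root.  Within each cycle the Witzig-Womersley friction
#' and convective-acceleration corrections are frozen from the completed
#' previous cycle (the first cycle bootstraps with the Poiseuille /
#' flat-profile closure, and vessels with fundamental Womersley number below
#' `config$alpha_threshold` always use that closure); the discarded initial
#' cycles absorb the transient.
#'
#' @param network An [arterial_network()]; terminal Windkessels are derived
#'   with defaults if not yet attached.
#' @param heart An [elastance_heart()].
#' @param config A [solver_config()].
#' @param gravity Logical: include the gravitational body force
#'   `A g cos(theta)` using the segment angles?
#' @param modulate_coronaries Logical: modulate the coronary segments' wall
#'   and terminal parameters with the normalised elastance?
#' @param inflow Optional prescribed root inflow replacing the ventricle:
#'   a function of time (s) returning ml/s, or a vector over one cycle
#'   (length `n_steps + 1`).  The cardiac bookkeeping (EDV/ESV/SV/EF) is not
#'   meaningful in this mode.
#' @param quiet Suppress per-cycle progress output?
#' @return An object of class `hemo_sim`: final-cycle nodal waveform matrices
#'   (`p`, `q`, `a` in mmHg, ml/s, mm^2; nodes by time), node metadata
#'   (`nodes` tibble), heart series and per-cycle summary (`cycles` tibble),
#'   convergence metrics, plus the inputs.
#' @examples
#' \donttest{
#' net <- derive_terminal_parameters(arterial_network(equine_segment_table()))
#' sim <- simulate_hemodynamics(net, config = solver_config(n_cycles = 2))
#' glance(sim)
#' }
#' @export
simulate_hemodynamics <- function(network, heart = elastance_heart(),
                                  config = solver_config(), gravity = FALSE,
                                  modulate_coronaries = TRUE, inflow = NULL,
                                  quiet = TRUE) {
  if (is.null(network$terminals)) network <- derive_terminal_parameters(network)
  blood <- network$blood
  law <- network$law
  period <- heart$period
  n_steps <- round(period / config$dt)
  dt <- period / n_steps

  mesh <- build_mesh(network, config, gravity = gravity)
  seg <- network$segments
  ns <- nrow(seg)
  t_grid <- (0:n_steps) * dt

  # per-segment fundamental Womersley number at the mid-tapered radius
  r_mid <- (seg$proximal_diameter_mm + seg$distal_diameter_mm) / 4 / 1000
  alpha_seg <- womersley_number(r_mid, heart$hr / 60, blood)
  womersley_segs <- which(alpha_seg > config$alpha_threshold)

  # heart elastance and coronary modulation tables
  ehat <- normalized_elastance(t_grid, heart)
  estar_si <- (heart$emin + (heart$emax - heart$emin) * ehat) * MMHG_PA / 1e-6

  delta_fac <- matrix(1, ns, n_steps + 1)
  tp <- mesh$windkessel
  wk_rfac <- matrix(1, nrow(tp), n_steps + 1)
  wk_cfac <- matrix(1, nrow(tp), n_steps + 1)
  if (modulate_coronaries) {
    cor_ids <- seg$segment_id[seg$region %in% "heart" & seg$is_terminal]
    for (id in cor_ids) {
      side <- if (grepl("dextra?$|dexter$", seg$name[seg$segment_id == id])) "right" else "left"
      mod <- coronary_modulation(t_grid, heart, side = side)
      srow <- which(seg$segment_id == id)
      trow <- which(tp$terminal_id == id)
      delta_fac[srow, ] <- mod$distensibility_factor
      wk_rfac[trow, ] <- mod$resistance_factor
      wk_cfac[trow, ] <- mod$distensibility_factor
    }
  }

  params <- list(
    a1 = law$a1, b1 = law$b1, pmaxc = mmhg_to_pa(law$p_max_c),
    pwidth = mmhg_to_pa(law$p_width), pref = mmhg_to_pa(law$p_ref),
    rho = blood$density, mu = blood$viscosity,
    dt = dt, theta = config$theta, newton_tol = config$newton_tol,
    dissipation = config$dissipation,
    max_newton_iter = as.integer(config$max_newton_iter),
    n_steps = as.integer(n_steps),
    emin = heart$emin * MMHG_PA / 1e-6, emax = heart$emax * MMHG_PA / 1e-6,
    v0 = heart$v0 * 1e-6, kappa = heart$kappa * 1e6,
    p_end = mmhg_to_pa(heart$p_end_diastolic),
    r_fill = rmmhg_to_si(heart$r_fill),
    estar = estar_si,
    windkessel = cbind(
      rmmhg_to_si(tp$R1), rmmhg_to_si(tp$R2), cmmhg_to_si(tp$CT)
    ),
    wk_rfac = wk_rfac, wk_cfac = wk_cfac, delta_fac = delta_fac,
    fric_src = matrix(0, mesh$total_nodes, n_steps + 1),
    conv_src = matrix(0, mesh$total_nodes, n_steps + 1),
    inflow = numeric(0)
  )
  if (!is.null(inflow)) {
    qv <- if (is.function(inflow)) inflow(t_grid) else rep_len(inflow, n_steps + 1)
    params$inflow <- qv * 1e-6
  }

  state <- list(
    p = rep(mmhg_to_pa(config$initial_p), mesh$total_nodes),
    q = rep(config$initial_q * 1e-6, mesh$total_nodes),
    v_lv = (heart$p_end_diastolic / heart$emin + heart$v0) * 1e-6,
    phase = 0L
  )

  cycles <- vector("list", config$n_cycles)
  p_prev <- NULL
  res <- NULL
  for (cyc in seq_len(config$n_cycles)) {
    if (cyc > 1) {
      src <- refresh_womersley_sources(
        res$q_hist, res$a_hist, mesh, womersley_segs, blood, period, config,
        conv_deviation = config$conv_deviation
      )
      params$fric_src <- src$fric
      params$conv_src <- src$conv
    }
    res <- solve_cycle_cpp(state, mesh, params)
    state <- res$state

    p_conv <- if (is.null(p_prev)) NA_real_ else {
      max(abs(res$p_hist - p_prev)) / (max(res$p_hist) - min(res$p_hist))
    }
    edv_ml <- res$edv * 1e6
    esv_ml <- res$esv * 1e6
    co <- mean(res$q_root[seq_len(n_steps)]) * 1e6 / 1000 * 60  # L/min
    cycles[[cyc]] <- tibble::tibble(
      cycle = cyc, edv = edv_ml, esv = esv_ml, sv = edv_ml - esv_ml,
      ef = (edv_ml - esv_ml) / edv_ml, co_l_min = co,
      waveform_change = p_conv,
      newton_mean = res$newton_total / n_steps, newton_max = res$newton_max
    )
    p_prev <- res$p_hist
    if (!quiet) {
      message(sprintf(
        "cycle %d: CO %.1f L/min, SV %.0f ml, EF %.1f%%, dP %.2g",
        cyc, co, edv_ml - esv_ml, 100 * (edv_ml - esv_ml) / edv_ml, p_conv
      ))
    }
  }

  nodes <- tibble::tibble(
    node = seq_len(mesh$total_nodes),
    segment_id = seg$segment_id[mesh$seg_of_node],
    segment_name = seg$name[mesh$seg_of_node],
    position_mm = mesh$x_node,
    radius_ref_mm = mesh$radius_ref * 1000,
    region = seg$region[mesh$seg_of_node],
    alpha = alpha_seg[mesh$seg_of_node],
    is_terminal_node = FALSE
  )
  term_last <- mesh$node_offset + mesh$n_nodes
  nodes$is_terminal_node[term_last[mesh$terminal_index >= 0]] <- TRUE

  structure(
    list(
      p = pa_to_mmhg(res$p_hist),
      q = res$q_hist * 1e6,
      a = res$a_hist * 1e6,  # mm^2
      time = t_grid,
      nodes = nodes,
      heart_series = tibble::tibble(
        time = t_grid,
        v_lv = res$v_lv * 1e6,
        p_lv = pa_to_mmhg(res$p_lv),
        q_root = res$q_root * 1e6,
        phase = c("isovolumic_contraction", "ejection", "relaxation", "filling")[res$phase + 1]
      ),
      cycles = dplyr::bind_rows(cycles),
      network = network,
      heart = heart,
      config = config,
      gravity = gravity,
      mesh = mesh,
      alpha_seg = alpha_seg,
      period = period,
      dt = dt
    ),
    class = "hemo_sim"
  )
}

#' @export
print.hemo_sim <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<hemo_sim> %d segments, %d nodes, %d cycles, gravity %s\n",
    nrow(x$network$segments), nrow(x$nodes), nrow(x$cycles),
    if (x$gravity) "on" else "off"
  ))
  cat(sprintf(
    "  CO %.1f L/min | SV %.0f ml | EF %.1f%% | root %s/%s mmHg (MAP %.0f)\n",
    g$co_l_min, g$sv_ml, g$ef_pct,
    formatC(g$systolic_mmHg, format = "f", digits = 0),
    formatC(g$diastolic_mmHg, format = "f", digits = 0), g$map_mmHg
  ))
  invisible(x)
}

#' Extract waveforms at a probe location
#'
#' @param sim A `hemo_sim` result.
#' @param segment_id Segment identifier (as in the segment table).
#' @param position_mm Arc position along the segment, mm; the nearest node is
#'   used (defaults to the proximal node).
#' @return A tibble with `time`, `p` (mmHg), `q` (ml/s), `a` (mm^2),
#'   `velocity` (m/s).
#' @export
probe_waveform <- function(sim, segment_id, position_mm = 0) {
  sel <- which(sim$nodes$segment_id == as.character(segment_id))
  if (length(sel) == 0) stop("no such segment: ", segment_id)
  node <- sel[which.min(abs(sim$nodes$position_mm[sel] - position_mm))]
  tibble::tibble(
    time = sim$time,
    segment_id = as.character(segment_id),
    position_mm = sim$nodes$position_mm[node],
    p = sim$p[node, ],
    q = sim$q[node, ],
    a = sim$a[node, ],
    velocity = sim$q[node, ] / sim$a[node, ]  # (ml/s)/mm^2 = m/s
  )
}
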