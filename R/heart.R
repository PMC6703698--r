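#' Time-varying elastance left ventricle
#'
#' Parameter container for the four-phase left-ventricle model that drives
#' the arterial tree: isovolumic contraction, ejection (with an internal
#' ventricular resistance entering through `kappa`), isovolumic relaxation
#' and passive filling.  Defaults are the equine values: `Emin = 0.01` and
#' `Emax = 0.26` mmHg/ml, dead volume `V0 = 0` ml, `kappa = 55e-6` s/ml,
#' end-diastolic pressure 16 mmHg, heart rate 40 bpm, systolic duration
#' 478 ms and a filling resistance of 0.003 mmHg.s/ml.
#'
#' @param emin,emax Minimal/maximal elastance, mmHg/ml.
#' @param v0 Dead volume, ml.
#' @param kappa Internal-resistance constant of the ejecting ventricle, s/ml.
#' @param p_end_diastolic End-diastolic pressure, mmHg.
#' @param hr Heart rate, beats per minute.
#' @param t_sys Systolic duration, s.
#' @param r_fill Filling resistance, mmHg.s/ml.
#' @return An object of class `elastance_heart`.
#' @examples
#' elastance_heart()
#' @export
elastance_heart <- function(emin = 0.01, emax = 0.26, v0 = 0, kappa = 55e-6,
                            p_end_diastolic = 16, hr = 40, t_sys = 0.478,
                            r_fill = 0.003) {
  stopifnot(emax > emin, emin > 0, hr > 0, t_sys > 0, t_sys < 60 / hr, r_fill > 0)
  structure(
    list(
      emin = emin, emax = emax, v0 = v0, kappa = kappa,
      p_end_diastolic = p_end_diastolic, hr = hr, t_sys = t_sys,
      r_fill = r_fill, period = 60 / hr
    ),
    class = "elastance_heart"
  )
}

#' @export
print.elastance_heart <- function(x, ...) {
  cat(sprintf(
    "<elastance_heart> Emin %g, Emax %g mmHg/ml, HR %g bpm, t_sys %g ms, kappa %g s/ml\n",
    x$emin, x$emax, x$hr, x$t_sys * 1000, x$kappa
  ))
  invisible(x)
}

# Normalised isovolumic elastance shape: double-Hill in s = t / t_sys with
# rise/decay exponents 1.32 / 21.9, normalised to unit peak.  The time scale
# anchors the printed systolic duration to the model's own end-systole: with
# the divisor 0.42 the coupled equine model closes the aortic valve (flow
# reversal, the end-systole definition used here) at t_sys.
.ehat_raw <- function(s) {
  s1 <- 0.269 / 0.42
  s2 <- 0.452 / 0.42
  g1 <- (s / s1)^1.32
  g2 <- (s / s2)^21.9
  (g1 / (1 + g1)) / (1 + g2)
}

.ehat_peak <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- stats::optimize(.ehat_raw, c(0.2, 1.2), maximum = TRUE)$objective
    }
    val
  }
})

#' Normalised elastance shape
#'
#' The normalised (unit-peak) isovolumic elastance curve as a function of
#' time in the cycle; zero at the cycle onset, peaking within systole and
#' decayed back to near zero at `t_sys`.
#'
#' @param t_in_cycle Time since cycle onset, s (vectorised).
#' @param heart An [elastance_heart()].
#' @return Values in `[0, 1]`.
#' @export
normalized_elastance <- function(t_in_cycle, heart = elastance_heart()) {
  t_in_cycle <- t_in_cycle %% heart$period
  .ehat_raw(t_in_cycle / heart$t_sys) / .ehat_peak()
}

#' Isovolumic elastance
#'
#' `E*(t) = Emin + (Emax - Emin) * ehat(t)`: the elastance a non-ejecting
#' (isovolumic) contraction would exhibit.
#'
#' @inheritParams normalized_elastance
#' @return Elastance in mmHg/ml.
#' @examples
#' isovolumic_elastance(0)  # Emin
#' @export
isovolumic_elastance <- function(t_in_cycle, heart = elastance_heart()) {
  heart$emin + (heart$emax - heart$emin) * normalized_elastance(t_in_cycle, heart)
}

#' Elastance of the ejecting ventricle
#'
#' `E = E* (1 - kappa Q)`: ejection flow reduces the apparent elastance
#' through the internal resistance of the ventricle.
#'
#' @param e_star Isovolumic elastance, mmHg/ml.
#' @param q Ejection flow, ml/s.
#' @param heart An [elastance_heart()].
#' @return Elastance in mmHg/ml.
#' @examples
#' ejecting_elastance(0.26, 1000)  # 0.2457
#' @export
ejecting_elastance <- function(e_star, q, heart = elastance_heart()) {
  e_star * (1 - heart$kappa * q)
}

#' Coronary wall/terminal modulation factors
#'
#' The coronary vessels are compressed by the contracting myocardium: their
#' resistance is scaled up, and compliance/distensibility scaled down, in
#' proportion to the local normalised elastance.  The right-side modulation
#' amplitude is one third of the left (ratio of maximal ventricular
#' pressures, about 3).
#'
#' @inheritParams normalized_elastance
#' @param side `"left"` or `"right"`.
#' @param gain Modulation gain at peak elastance for the left side.
#' @return A list with `resistance_factor` and `distensibility_factor`
#'   (multiplicative, both 1 in diastole).
#' @export
coronary_modulation <- function(t_in_cycle, heart = elastance_heart(),
                                side = c("left", "right"), gain = 1) {
  side <- match.arg(side)
  amp <- if (side == "left") gain else gain / 3
  ehat <- normalized_elastance(t_in_cycle, heart)
  list(
    resistance_factor = 1 + amp * ehat,
    distensibility_factor = 1 / (1 + amp * ehat)
  )
}

#' One explicit step of the four-phase cardiac cycle
#'
#' Advances the 0D left-ventricle state machine by `dt` against a prescribed
#' aortic root pressure.  Phases follow the printed cycle order: isovolumic
#' contraction until ventricular pressure exceeds the root pressure (valve
#' opens), ejection with the ejecting-elastance coupling, valve closure when
#' the ejection flow falls below zero, isovolumic relaxation, and passive
#' filling (flow `(P_end_diastolic - P_LV)/R_fill`) once ventricular pressure
#' drops below the end-diastolic pressure.  At a cycle boundary the
#' end-diastolic volume is carried over.
#'
#' This function is the 0D building block used for standalone heart runs
#' ([simulate_heart_windkessel()]); the full 1D solver embeds the identical
#' state machine in its implicit root boundary condition.
#'
#' @param state List with `t_cycle`, `phase`, `v_lv` (ml) plus bookkeeping
#'   fields; see [new_cardiac_state()].
#' @param aortic_root_p Aortic root pressure, mmHg.
#' @param heart An [elastance_heart()].
#' @param dt Time step, s.
#' @return List with the advanced `state` and the flow into the aorta
#'   `q_out` (ml/s) over the step.
#' @export
cardiac_cycle_step <- function(state, aortic_root_p, heart, dt) {
  t_new <- state$t_cycle + dt
  cycle_rollover <- t_new >= heart$period - 1e-12
  if (cycle_rollover) {
    t_new <- t_new - heart$period
    state$edv <- state$v_lv
    state$phase <- "isovolumic_contraction"
  }
  e_star <- isovolumic_elastance(t_new, heart)
  q_out <- 0

  if (state$phase == "isovolumic_contraction") {
    p_lv <- e_star * (state$v_lv - heart$v0)
    if (p_lv > aortic_root_p) {
      state$phase <- "ejection"
    }
    state$p_lv <- p_lv
  }
  if (state$phase == "ejection") {
    # solve P_ao = E*(1 - kappa Q)(V - dt Q - V0) for Q (quadratic, take the
    # root continuous with Q = 0 at kappa -> 0)
    v <- state$v_lv
    a <- heart$kappa * dt * e_star
    b <- -e_star * (dt + heart$kappa * (v - heart$v0))
    cc <- e_star * (v - heart$v0) - aortic_root_p
    disc <- b^2 - 4 * a * cc
    q_out <- if (a > 0 && disc >= 0) {
      (-b - sqrt(disc)) / (2 * a)
    } else {
      -cc / b
    }
    if (q_out < 0) {
      # valve closes: retain the interpolated crossing in the volume ledger
      q_out <- 0
      state$phase <- "relaxation"
      state$esv <- state$v_lv
      state$p_lv <- e_star * (state$v_lv - heart$v0)
    } else {
      state$v_lv <- v - dt * q_out
      state$p_lv <- ejecting_elastance(e_star, q_out, heart) * (state$v_lv - heart$v0)
      state$esv <- state$v_lv
    }
  }
  if (state$phase == "relaxation") {
    state$p_lv <- e_star * (state$v_lv - heart$v0)
    if (state$p_lv < heart$p_end_diastolic) {
      state$phase <- "filling"
    }
  }
  if (state$phase == "filling") {
    # implicit update of dV/dt = (P_ed - E* (V - V0)) / R_fill
    v_new <- (state$v_lv + dt / heart$r_fill * (heart$p_end_diastolic + e_star * heart$v0)) /
      (1 + dt * e_star / heart$r_fill)
    state$v_lv <- v_new
    state$p_lv <- e_star * (v_new - heart$v0)
  }
  state$t_cycle <- t_new
  list(state = state, q_out = q_out)
}

#' Fresh cardiac state at cycle onset
#'
#' @param heart An [elastance_heart()].
#' @param v_lv Initial ventricular volume, ml; defaults to the volume at
#'   which minimal elastance balances the end-diastolic pressure.
#' @return A state list for [cardiac_cycle_step()].
#' @export
new_cardiac_state <- function(heart = elastance_heart(), v_lv = NULL) {
  if (is.null(v_lv)) v_lv <- heart$p_end_diastolic / heart$emin + heart$v0
  list(
    t_cycle = 0, phase = "isovolumic_contraction",
    v_lv = v_lv, p_lv = heart$emin * (v_lv - heart$v0),
    edv = v_lv, esv = NA_real_
  )
}

#' Simulate the heart coupled to a single three-element Windkessel
#'
#' A 0D companion model: the four-phase ventricle ejecting into one
#' Windkessel (`R1`, `R2`, `CT`) standing in for the whole arterial tree.
#' Useful for parameter exploration and as a fast cross-check of the coupled
#' boundary treatment in the 1D solver.
#'
#' @param heart An [elastance_heart()].
#' @param r1,r2 Proximal/distal resistance, mmHg.s/ml.
#' @param ct Compliance, ml/mmHg.
#' @param n_cycles Number of cycles to run.
#' @param dt Time step, s.
#' @param p0 Initial Windkessel (distal) pressure, mmHg.
#' @return A tibble with time, phase, ventricular volume and pressure, root
#'   pressure and aortic flow, plus per-cycle `edv`, `esv`, `sv`, `ef`
#'   attributes in `summary`.
#' @export
simulate_heart_windkessel <- function(heart = elastance_heart(),
                                      r1 = 0.009, r2 = 0.131, ct = 12,
                                      n_cycles = 8, dt = 5e-4, p0 = 75) {
  n_steps <- round(heart$period / dt)
  state <- new_cardiac_state(heart)
  p_wk <- p0  # pressure on the compliance
  rows <- vector("list", n_cycles)
  summaries <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    tv <- numeric(n_steps)
    qv <- numeric(n_steps)
    pv <- numeric(n_steps)
    vv <- numeric(n_steps)
    prootv <- numeric(n_steps)
    edv_c <- state$v_lv
    for (i in seq_len(n_steps)) {
      # valve opening is decided at q -> 0+ (root pressure = p_wk); during
      # established ejection the root pressure seen by the ventricle is
      # p_wk + R1 q, solved by damped fixed-point iteration on q
      res <- cardiac_cycle_step(state, p_wk, heart, dt)
      if (res$state$phase == "ejection") {
        st_ej <- state
        st_ej$phase <- "ejection"
        q_guess <- res$q_out
        for (it in 1:300) {
          res <- cardiac_cycle_step(st_ej, p_wk + r1 * q_guess, heart, dt)
          if (abs(res$q_out - q_guess) < 1e-9) break
          q_guess <- 0.5 * (q_guess + res$q_out)
        }
      }
      state <- res$state
      q <- res$q_out
      # implicit update of CT dP/dt = Q - P / R2
      p_wk <- (p_wk + dt / ct * q) / (1 + dt / (ct * r2))
      tv[i] <- (cyc - 1) * heart$period + state$t_cycle
      qv[i] <- q
      pv[i] <- state$p_lv
      vv[i] <- state$v_lv
      prootv[i] <- if (q > 0) p_wk + r1 * q else p_wk
    }
    sv_c <- edv_c - min(vv)
    summaries[[cyc]] <- tibble::tibble(
      cycle = cyc, edv = edv_c, esv = min(vv), sv = sv_c,
      ef = sv_c / edv_c,
      co_l_min = sum(qv) * dt / heart$period * 60 / 1000
    )
    rows[[cyc]] <- tibble::tibble(
      time = tv, q_aorta = qv, p_lv = pv, v_lv = vv, p_root = prootv,
      cycle = cyc
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- dplyr::bind_rows(summaries)
  out
}
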