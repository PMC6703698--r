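# Programmatic fixtures: toy networks and synthetic waveform sets, so every
# operation is testable without the packaged anatomy.

#' Generate a toy arterial network
#'
#' Small networks with known analytic behaviour: a single uniform tube, a
#' symmetric bifurcation, or a three-generation symmetric tree (7 segments,
#' 4 terminals).  With `terminal_load = "matched"` the terminal resistances
#' are set to the characteristic impedance so the outlets are
#' reflection-free; `"windkessel"` uses a physiological split; `"blocked"`
#' gives near-infinite terminal resistance.
#'
#' @param topology `"single_tube"`, `"symmetric_bifurcation"` or
#'   `"three_generation_tree"`.
#' @param length_mm Segment length.
#' @param diameter_mm Root diameter (daughters scaled for a matched junction).
#' @param angle_1d Branching angle (degrees) applied to all segments.
#' @param distensibility Distensibility in 1e-3/mmHg (all segments).
#' @param terminal_load `"matched"`, `"windkessel"` or `"blocked"`.
#' @param law A [compliance_law()].
#' @param blood A [blood_properties()].
#' @return An [arterial_network()] with terminal parameters attached.
#' @examples
#' toy_network("three_generation_tree")
#' @export
toy_network <- function(topology = c(
                          "single_tube", "symmetric_bifurcation",
                          "three_generation_tree"
                        ),
                        length_mm = 200, diameter_mm = 20, angle_1d = 0,
                        distensibility = 4, terminal_load = c(
                          "matched", "windkessel", "blocked"
                        ),
                        law = compliance_law(), blood = blood_properties()) {
  topology <- match.arg(topology)
  terminal_load <- match.arg(terminal_load)
  # matched symmetric daughters: equal admittance requires
  # 2 * A_d / PWV_d = A_p / PWV_p; with a shared distensibility column the
  # reference PWV is diameter-independent, so A_d = A_p / 2.
  d_daughter <- diameter_mm / sqrt(2)
  d_grand <- diameter_mm / 2

  row <- function(id, parent, d, len = length_mm) {
    tibble::tibble(
      segment_id = id, name = paste("segment", id), parent_id = parent,
      angle_1d = angle_1d, length_mm = len, mean_diameter_mm = d,
      proximal_diameter_mm = d, distal_diameter_mm = d,
      distensibility_1e3_mmHg = distensibility, region = "other"
    )
  }
  segs <- switch(topology,
    single_tube = row("1", NA_character_, diameter_mm),
    symmetric_bifurcation = dplyr::bind_rows(
      row("1", NA_character_, diameter_mm),
      row("2", "1", d_daughter),
      row("3", "1", d_daughter)
    ),
    three_generation_tree = dplyr::bind_rows(
      row("1", NA_character_, diameter_mm),
      row("2", "1", d_daughter),
      row("3", "1", d_daughter),
      row("4", "2", d_grand),
      row("5", "2", d_grand),
      row("6", "3", d_grand),
      row("7", "3", d_grand)
    )
  )
  net <- arterial_network(segs, law = law, blood = blood)
  term <- net$segments[net$segments$is_terminal, ]
  zc <- vapply(seq_len(nrow(term)), function(i) {
    .zc_of_area(term$area_dist_m2[i], term$delta_mmHg[i], law, blood)
  }, numeric(1))
  rt <- switch(terminal_load,
    matched = zc,
    windkessel = zc / 0.07,   # R1 about 7 percent of RT
    blocked = zc * 1e6
  )
  r1 <- pmin(zc, 0.9 * rt)
  net$terminals <- tibble::tibble(
    terminal_id = term$segment_id,
    region = term$region,
    RT = rt, R1 = r1, R2 = rt - r1,
    CT = if (terminal_load == "blocked") rep(1e-3, nrow(term)) else 0.2 / rt
  )
  net
}

#' Generate synthetic waveform sets
#'
#' Constructed waveform pairs with an exactly known property, for exercising
#' the analysis operations: `"forward_only"` satisfies `dP = Zc dQ` sample by
#' sample (so the backward wave power vanishes identically),
#' `"shifted_pair"` is one pulse observed at two sites with a known pure
#' delay, and `"noisy_beats"` is a repeated beat with additive Gaussian noise
#' under a fixed seed.
#'
#' @param kind `"forward_only"`, `"shifted_pair"` or `"noisy_beats"`.
#' @param n_samples Samples per cycle.
#' @param period Cycle duration, s.
#' @param zc Characteristic impedance for `"forward_only"`, mmHg.s/ml.
#' @param delay Delay between the probe pair, s.
#' @param n_beats Number of beats for `"noisy_beats"`.
#' @param noise_sd Noise standard deviation (fraction of pulse amplitude).
#' @param seed Random seed for the noise.
#' @return A list with the waveforms and the generation parameters.
#' @export
make_synthetic_waveforms <- function(kind = c(
                                       "forward_only", "shifted_pair",
                                       "noisy_beats"
                                     ),
                                     n_samples = 500, period = 1.5, zc = 0.01,
                                     delay = 0.04, n_beats = 10,
                                     noise_sd = 0.01, seed = 0) {
  kind <- match.arg(kind)
  time <- seq(0, period, length.out = n_samples + 1)[-(n_samples + 1)]
  pulse <- function(t) {
    s <- (t %% period) / period
    wrap <- function(x) (x + 0.5) %% 1 - 0.5  # exactly periodic in s
    80 + 40 * exp(-0.5 * (wrap(s - 0.22) / 0.09)^2) +
      10 * exp(-0.5 * (wrap(s - 0.45) / 0.12)^2)
  }
  switch(kind,
    forward_only = {
      p <- pulse(time)
      q <- (p - min(p)) / zc
      list(kind = kind, time = time, p = p, q = q, zc = zc, period = period)
    },
    shifted_pair = {
      list(
        kind = kind, time = time,
        p1 = pulse(time), p2 = pulse(time - delay),
        delay = delay, period = period
      )
    },
    noisy_beats = {
      set.seed(seed)
      tt <- seq(0, n_beats * period, length.out = n_beats * n_samples + 1)
      tt <- tt[-length(tt)]
      clean <- pulse(tt)
      list(
        kind = kind, time = tt, clean = clean,
        noisy = clean + stats::rnorm(length(tt), 0, noise_sd * 40),
        triggers = (0:(n_beats)) * period,
        noise_sd = noise_sd, seed = seed, period = period
      )
    }
  )
}

#' Write a segment table to CSV
#'
#' Writes the same CSV dialect as the packaged equine table, so generated
#' fixtures round-trip through [read_segment_table()].
#'
#' @param segments A segment table (tibble) or an [arterial_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  if (inherits(segments, "arterial_network")) segments <- segments$segments
  cols <- c(
    "segment_id", "name", "parent_id", "angle_1d", "length_mm",
    "mean_diameter_mm", "proximal_diameter_mm", "distal_diameter_mm",
    "distensibility_1e3_mmHg", "region"
  )
  readr::write_csv(segments[, cols], path, na = "")
  invisible(path)
}
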