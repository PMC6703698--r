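options(testthat.progress.max_fails = 1000)

# Shared fixtures.  The full equine runs are expensive (~1 min each), so they
# are computed once per test session and reused by every file that needs them.

.run_cache <- new.env(parent = emptyenv())

equine_network_cached <- function() {
  if (is.null(.run_cache$net)) {
    .run_cache$net <- suppressWarnings(
      derive_terminal_parameters(arterial_network(equine_segment_table()))
    )
  }
  .run_cache$net
}

equine_sim_cached <- function(gravity = FALSE) {
  key <- if (gravity) "sim_grav" else "sim_nograv"
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- simulate_hemodynamics(
      equine_network_cached(),
      config = solver_config(n_cycles = 8),
      gravity = gravity, quiet = TRUE
    )
  }
  .run_cache[[key]]
}

# aortic pressure probes (proximal + mid of each thoracic/abdominal aortic
# segment) with cumulative arc distance from the arch, for foot-to-foot PWV
aortic_probe_set <- function(sim) {
  seg_path <- c("71", "72", "74", "76", "78", "80", "82", "85", "87")
  net <- sim$network
  probes <- list()
  dists <- numeric(0)
  dist0 <- 0
  for (id in seg_path) {
    len <- net$segments$length_mm[net$segments$segment_id == id]
    for (frac in c(0, 0.5)) {
      wf <- probe_waveform(sim, id, frac * len)
      probes[[length(probes) + 1]] <- wf$p
      dists <- c(dists, dist0 + wf$position_mm[1])
    }
    dist0 <- dist0 + len
  }
  list(p = probes, distance_mm = dists)
}
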