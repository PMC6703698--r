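REGION_LEVELS <- c("heart", "brain", "muscle", "kidney", "splanchnic", "other")

#' Packaged equine arterial tree segment table
#'
#' Anatomical description of the 117-segment equine arterial tree: per-segment
#' connectivity, branching angle in the sagittal 1D plane, length, mean and
#' tapered (proximal/distal) lumen diameters, distensibility at the reference
#' pressure, and, for the 62 terminal segments, the body region used for the
#' flow-distribution targets (heart, brain, muscle, kidney, splanchnic, other).
#' Extra 5-cm terminal stubs carry a "b" suffix in their id (58b, 69b, 99b,
#' 112b).  One source row prints a mean diameter of 1 mm against tapered
#' diameters of 9.71 mm for segment 112b; the packaged table uses the tapered
#' value, consistent with the mirrored left-side segment 99b.
#'
#' @return A tibble with one row per segment.
#' @examples
#' tab <- equine_segment_table()
#' nrow(tab)  # 117
#' @export
equine_segment_table <- function() {
  path <- system.file("extdata", "equine_arterial_tree.csv",
    package = "equihemo", mustWork = TRUE
  )
  read_segment_table(path)
}

#' Read a segment table from CSV
#'
#' @param path Path to a CSV file with the segment-table schema (see
#'   [equine_segment_table()] for the column layout).
#' @return A tibble of segments.
#' @export
read_segment_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      segment_id = readr::col_character(),
      name = readr::col_character(),
      parent_id = readr::col_character(),
      angle_1d = readr::col_double(),
      length_mm = readr::col_double(),
      mean_diameter_mm = readr::col_double(),
      proximal_diameter_mm = readr::col_double(),
      distal_diameter_mm = readr::col_double(),
      distensibility_1e3_mmHg = readr::col_double(),
      region = readr::col_character()
    ),
    progress = FALSE
  )
}

segment_schema_cols <- c(
  "segment_id", "parent_id", "angle_1d", "length_mm", "mean_diameter_mm",
  "proximal_diameter_mm", "distal_diameter_mm", "distensibility_1e3_mmHg"
)

#' Assemble and validate an arterial network
#'
#' Builds the rooted-tree representation of an arterial network from a segment
#' table: connectivity, junction map, terminal set, per-segment wall-law
#' coefficients and gravity projections.  The table is validated against the
#' schema invariants (unique ids, single root, acyclic connectivity, positive
#' lengths and distensibilities, non-expanding tapering, angles in [0, 360)).
#'
#' @param segments A segment table (see [equine_segment_table()]); a `name`
#'   column and per-terminal `region` labels are optional for toy networks.
#' @param law A [compliance_law()].
#' @param blood A [blood_properties()].
#' @return An object of class `arterial_network`.
#' @examples
#' net <- arterial_network(equine_segment_table())
#' net
#' @export
arterial_network <- function(segments, law = compliance_law(),
                             blood = blood_properties()) {
  segments <- tibble::as_tibble(segments)
  missing_cols <- setdiff(segment_schema_cols, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"name" %in% names(segments)) segments$name <- segments$segment_id
  if (!"region" %in% names(segments)) segments$region <- NA_character_

  ids <- segments$segment_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate segment id(s): ", paste(unique(dup), collapse = ", "))

  bad <- which(!(segments$length_mm > 0))
  if (length(bad) > 0) stop("non-positive length in segment(s): ", paste(ids[bad], collapse = ", "))
  bad <- which(!(segments$distensibility_1e3_mmHg > 0))
  if (length(bad) > 0) stop("non-positive distensibility in segment(s): ", paste(ids[bad], collapse = ", "))
  bad <- which(segments$proximal_diameter_mm < segments$distal_diameter_mm - 1e-9)
  if (length(bad) > 0) {
    stop("expanding taper (distal > proximal diameter) in segment(s): ",
      paste(ids[bad], collapse = ", "))
  }
  bad <- which(segments$angle_1d < 0 | segments$angle_1d >= 360)
  if (length(bad) > 0) stop("angle outside [0, 360) in segment(s): ", paste(ids[bad], collapse = ", "))

  is_root <- is.na(segments$parent_id)
  if (sum(is_root) != 1) {
    stop("expected exactly one root segment (parent_id = NA), found ", sum(is_root))
  }
  root_id <- ids[is_root]
  orphan <- setdiff(stats::na.omit(segments$parent_id), ids)
  if (length(orphan) > 0) stop("parent id(s) not present in table: ", paste(orphan, collapse = ", "))

  children <- split(ids[!is_root], factor(segments$parent_id[!is_root], levels = ids))
  # reachability / cycle check by breadth-first traversal from the root
  seen <- character(0)
  frontier <- root_id
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
    if (length(seen) > length(ids)) stop("cycle detected in segment connectivity")
  }
  unreachable <- setdiff(ids, seen)
  if (length(unreachable) > 0) {
    stop("segment(s) not reachable from root: ", paste(unreachable, collapse = ", "))
  }

  n_children <- lengths(children)[ids]
  segments$is_terminal <- n_children == 0
  bad <- which(segments$is_terminal &
    (is.na(segments$region) | !segments$region %in% REGION_LEVELS))
  if (length(bad) > 0) {
    segments$region[bad] <- "other"
  }
  segments$cos_theta <- gravity_projection(segments$angle_1d)
  segments$delta_mmHg <- segments$distensibility_1e3_mmHg * 1e-3
  segments$area_prox_m2 <- pi / 4 * (segments$proximal_diameter_mm / 1000)^2
  segments$area_dist_m2 <- pi / 4 * (segments$distal_diameter_mm / 1000)^2

  structure(
    list(
      segments = segments,
      children = children,
      root_id = root_id,
      terminal_ids = ids[segments$is_terminal],
      law = law,
      blood = blood
    ),
    class = "arterial_network"
  )
}

#' @export
print.arterial_network <- function(x, ...) {
  cat(sprintf(
    "<arterial_network> %d segments, %d terminals, root '%s'\n",
    nrow(x$segments), length(x$terminal_ids), x$root_id
  ))
  if (!is.null(x$terminals)) {
    cat(sprintf(
      "  terminal Windkessels derived (parallel RT = %.4g mmHg.s/ml)\n",
      1 / sum(1 / x$terminals$RT)
    ))
  }
  invisible(x)
}

#' Load an arterial network from a CSV segment table
#'
#' @param path Path to a segment-table CSV.
#' @inheritParams arterial_network
#' @return An `arterial_network`.
#' @export
load_network <- function(path, law = compliance_law(), blood = blood_properties()) {
  arterial_network(read_segment_table(path), law = law, blood = blood)
}

#' Gravity projection of a segment axis
#'
#' Cosine of the angle between a segment's flow axis and the downward
#' vertical, from the branching angle in the sagittal 1D plane.  The
#' convention is 0 degrees = horizontal (caudal) with angles increasing
#' counterclockwise, so the downward component of the unit flow axis is
#' `-sin(angle)`: the horizontally running descending aorta (0 degrees) is
#' gravity-neutral, head-going vessels (around 90-135 degrees) are
#' gravity-opposed, and limb vessels (around 240-335 degrees) are
#' gravity-assisted.
#'
#' @param angle_1d Branching angle(s) in degrees.
#' @return `cos(theta)` in `[-1, 1]`, positive where gravity aids flow.
#' @examples
#' gravity_projection(c(0, 90, 270))  # 0, -1, +1
#' @export
gravity_projection <- function(angle_1d) {
  -sin(angle_1d * pi / 180)
}

# delta (1/mmHg): tabulated distensibility when present, inverse-power PWV law
# with the global scale factor otherwise.
segment_delta_mmhg <- function(law, blood, d_mean_mm = NULL, distensibility_ref = NULL) {
  wall_delta_si(law, blood, d_mean_mm, distensibility_ref) * MMHG_PA
}

#' Characteristic impedance of a vessel cross-section
#'
#' `Zc = rho * PWV / A` with the local PWV taken from the wall law at the
#' reference pressure.
#'
#' @param diameter_mm Lumen diameter at the cross-section, mm.
#' @param distensibility_ref Tabulated distensibility in 1e-3/mmHg, or `NULL`
#'   to use the diameter-based law (then `d_mean_mm` must be given).
#' @param d_mean_mm Mean segment diameter for the diameter-based law, mm.
#' @param p Pressure at which to evaluate, mmHg.
#' @param law A [compliance_law()].
#' @param blood A [blood_properties()].
#' @return Impedance in mmHg.s/ml.
#' @export
characteristic_impedance <- function(diameter_mm, distensibility_ref = NULL,
                                     d_mean_mm = diameter_mm,
                                     p = NULL,
                                     law = compliance_law(),
                                     blood = blood_properties()) {
  stopifnot(all(diameter_mm > 0))
  if (is.null(p)) p <- law$p_ref
  area <- pi / 4 * (diameter_mm / 1000)^2
  delta <- segment_delta_mmhg(law, blood, d_mean_mm, distensibility_ref)
  pwv <- local_pwv(p, area, delta, law, blood)
  rsi_to_mmhg(blood$density * pwv / area)
}

#' Reflection coefficient at a junction
#'
#' Admittance mismatch `Gamma = (Yp - sum(Yd)) / (Yp + sum(Yd))` with
#' `Y = 1/Zc`; zero for a matched junction, tending to -1 as the daughters'
#' total admittance grows without bound.
#'
#' @param parent_zc Characteristic impedance of the parent at its distal end.
#' @param daughter_zcs Impedances of the daughters at their proximal ends.
#' @return Dimensionless reflection coefficient in (-1, 1).
#' @examples
#' reflection_coefficient(1, 3)  # 0.5
#' @export
reflection_coefficient <- function(parent_zc, daughter_zcs) {
  stopifnot(parent_zc > 0, all(daughter_zcs > 0))
  if (length(daughter_zcs) == 0) stop("junction has no daughter vessels")
  yp <- 1 / parent_zc
  yd <- sum(1 / daughter_zcs)
  (yp - yd) / (yp + yd)
}

# Zc (mmHg.s/ml) at an arbitrary cross-sectional area using a segment row's
# wall coefficients at the reference pressure.
.zc_of_area <- function(area_m2, delta_mmHg, law, blood) {
  pwv <- local_pwv(law$p_ref, area_m2, delta_mmHg, law, blood)
  rsi_to_mmhg(blood$density * pwv / area_m2)
}

#' Reflection coefficients of all junctions of a network
#'
#' Evaluates the forward reflection coefficient at every junction from the
#' parent's distal and the daughters' proximal tapered areas at the reference
#' pressure.
#'
#' @param network An [arterial_network()].
#' @return A tibble with columns `parent_id`, `daughters`, `gamma`.
#' @export
junction_reflections <- function(network) {
  seg <- network$segments
  idx <- stats::setNames(seq_len(nrow(seg)), seg$segment_id)
  parents <- names(network$children)[lengths(network$children) > 0]
  rows <- lapply(parents, function(p) {
    ds <- network$children[[p]]
    zp <- .zc_of_area(seg$area_dist_m2[idx[p]], seg$delta_mmHg[idx[p]],
      network$law, network$blood)
    zd <- vapply(ds, function(d) {
      .zc_of_area(seg$area_prox_m2[idx[d]], seg$delta_mmHg[idx[d]],
        network$law, network$blood)
    }, numeric(1))
    tibble::tibble(
      parent_id = p,
      daughters = paste(ds, collapse = "+"),
      gamma = reflection_coefficient(zp, zd)
    )
  })
  dplyr::bind_rows(rows)
}

#' Assign or verify tapered areas that minimise junction reflections
#'
#' Vessel tapering is chosen so that the forward reflection coefficient is
#' small at every junction, subject to three conditions: the measured area is
#' the average of the proximal and distal areas of each segment, a daughter's
#' proximal area does not exceed its parent's distal area, and each segment's
#' distal area does not exceed its proximal area.  For a table that already
#' carries tapered diameters (the packaged equine tree) this verifies them;
#' otherwise proximal/distal areas are assigned by constrained minimisation of
#' the summed squared reflection coefficients, initialised from linear
#' tapering.
#'
#' @param network An [arterial_network()].
#' @param max_gamma Admissible absolute reflection coefficient.
#' @return The network, with a `junction_gamma` tibble attached and (when
#'   optimisation ran) updated proximal/distal diameters.
#' @export
apply_tapering <- function(network, max_gamma = 0.2) {
  seg <- network$segments
  has_taper <- any(abs(seg$proximal_diameter_mm - seg$distal_diameter_mm) > 1e-12)
  if (!has_taper || any(seg$proximal_diameter_mm <= 0)) {
    network <- .optimise_tapering(network)
    seg <- network$segments
  }
  gam <- junction_reflections(network)
  network$junction_gamma <- gam
  viol <- gam[abs(gam$gamma) >= max_gamma, ]
  if (nrow(viol) > 0) {
    warning(
      "reflection coefficient >= ", max_gamma, " at junction(s): ",
      paste(sprintf("%s->%s (%.3f)", viol$parent_id, viol$daughters, viol$gamma),
        collapse = ", ")
    )
  }
  network
}

# Constrained minimisation of sum(Gamma^2): one parameter per segment,
# s = A_in / A_mean - 1 in [0, smax]; A_out = 2*A_mean - A_in preserves the
# measured mean area.  The cross-junction ordering constraint (daughter A_in
# <= parent A_out) enters as a quadratic penalty.
.optimise_tapering <- function(network) {
  seg <- network$segments
  ids <- seg$segment_id
  idx <- stats::setNames(seq_along(ids), ids)
  a_mean <- pi / 4 * (seg$mean_diameter_mm / 1000)^2
  parents <- names(network$children)[lengths(network$children) > 0]

  objective <- function(s) {
    a_in <- a_mean * (1 + s)
    a_out <- a_mean * (1 - s)
    total <- 0
    for (p in parents) {
      ds <- network$children[[p]]
      zp <- .zc_of_area(a_out[idx[p]], seg$delta_mmHg[idx[p]], network$law, network$blood)
      zd <- vapply(ds, function(d) {
        .zc_of_area(a_in[idx[d]], seg$delta_mmHg[idx[d]], network$law, network$blood)
      }, numeric(1))
      total <- total + reflection_coefficient(zp, zd)^2
      total <- total + 1e4 * sum(pmax(0, a_in[idx[ds]] - a_out[idx[p]])^2 / a_mean[idx[p]]^2)
    }
    total
  }

  fit <- stats::optim(rep(0.05, length(ids)), objective,
    method = "L-BFGS-B", lower = 0, upper = 0.6,
    control = list(maxit = 500)
  )
  s <- fit$par
  seg$proximal_diameter_mm <- sqrt(4 / pi * a_mean * (1 + s)) * 1000
  seg$distal_diameter_mm <- sqrt(4 / pi * a_mean * (1 - s)) * 1000
  seg$area_prox_m2 <- a_mean * (1 + s)
  seg$area_dist_m2 <- a_mean * (1 - s)
  network$segments <- seg
  network
}

#' Derive three-element Windkessel parameters for all terminal segments
#'
#' Allocates total peripheral resistance and terminal compliance over the
#' terminal segments.  The parallel combination of all terminal resistances
#' equals `total_resistance` (default 0.14 mmHg.s/ml) and regional conductance
#' shares follow `flow_fractions` (defaults: heart 5, brain 10, muscle 15,
#' kidney 20, splanchnic 30, other 20 percent); within a region each terminal
#' receives conductance proportional to its distal cross-sectional area.
#' `R1` is set to the characteristic impedance of the terminal segment
#' (minimal high-frequency reflection) and `R2 = RT - R1`; should `R1` reach
#' `RT` it is clamped to `0.9 * RT` with a warning.  Terminal compliances are
#' distributed proportionally to the distal area compliance and scaled so
#' their sum is `compliance_fraction` (default 20 percent) of the total
#' systemic vascular compliance (segment volume compliances plus terminal
#' compliances).
#'
#' @param network An [arterial_network()].
#' @param total_resistance Parallel combination of terminal resistances,
#'   mmHg.s/ml.
#' @param flow_fractions Named fractions per region, summing to 1.
#' @param compliance_fraction Fraction of total systemic compliance assigned
#'   to the terminal Windkessels.
#' @return The network with a `terminals` tibble attached (columns
#'   `terminal_id`, `region`, `RT`, `R1`, `R2`, `CT` in mmHg.s/ml and
#'   ml/mmHg).
#' @examples
#' net <- derive_terminal_parameters(arterial_network(equine_segment_table()))
#' 1 / sum(1 / net$terminals$RT)  # 0.14
#' @export
derive_terminal_parameters <- function(network,
                                       total_resistance = 0.14,
                                       flow_fractions = c(
                                         heart = 0.05, brain = 0.10,
                                         muscle = 0.15, kidney = 0.20,
                                         splanchnic = 0.30, other = 0.20
                                       ),
                                       compliance_fraction = 0.20) {
  seg <- network$segments
  term <- seg[seg$is_terminal, ]
  regions_present <- unique(term$region)
  fr <- flow_fractions[regions_present]
  if (anyNA(fr)) stop("flow_fractions missing region(s): ",
    paste(regions_present[is.na(fr)], collapse = ", "))
  fr <- fr / sum(fr)  # renormalise over the regions actually present
  if (abs(sum(flow_fractions) - 1) > 1e-8 && length(regions_present) == length(flow_fractions)) {
    stop("flow_fractions must sum to 1")
  }

  g_total <- 1 / total_resistance
  g_region <- fr * g_total
  area_d <- term$area_dist_m2
  g_i <- numeric(nrow(term))
  for (r in regions_present) {
    in_r <- term$region == r
    g_i[in_r] <- g_region[[r]] * area_d[in_r] / sum(area_d[in_r])
  }
  rt <- 1 / g_i

  z_c <- vapply(seq_len(nrow(term)), function(i) {
    .zc_of_area(term$area_dist_m2[i], term$delta_mmHg[i], network$law, network$blood)
  }, numeric(1))
  r1 <- z_c
  clamped <- r1 >= rt
  if (any(clamped)) {
    warning("R1 = Zc >= RT for terminal(s) ",
      paste(term$segment_id[clamped], collapse = ", "),
      "; clamping R1 to 0.9*RT")
    r1[clamped] <- 0.9 * rt[clamped]
  }
  r2 <- rt - r1

  # volume compliance of every segment at reference pressure:
  # integral of C_A over length with linearly tapering diameter
  cp_ref <- pressure_compliance_factor(network$law$p_ref, network$law)
  d_in <- seg$proximal_diameter_mm / 1000
  d_out <- seg$distal_diameter_mm / 1000
  vol_int <- seg$length_mm / 1000 * pi / 12 * (d_in^2 + d_in * d_out + d_out^2)
  cv_seg <- sum(vol_int * (seg$delta_mmHg / MMHG_PA) * cp_ref)  # m^3/Pa
  ct_total <- cv_seg * compliance_fraction / (1 - compliance_fraction)

  ca_dist <- term$area_dist_m2 * (term$delta_mmHg / MMHG_PA) * cp_ref
  ct <- ct_total * ca_dist / sum(ca_dist)

  network$terminals <- tibble::tibble(
    terminal_id = term$segment_id,
    region = term$region,
    RT = rt, R1 = r1, R2 = r2,
    CT = csi_to_mmhg(ct)
  )
  network$compliance_summary <- tibble::tibble(
    segment_volume_compliance = csi_to_mmhg(cv_seg),
    terminal_compliance = csi_to_mmhg(ct_total),
    total_systemic_compliance = csi_to_mmhg(cv_seg + ct_total)
  )
  network
}

#' Terminal Windkessel parameter table
#'
#' @param network An [arterial_network()] after [derive_terminal_parameters()].
#' @return Tibble of per-terminal `R1`, `R2`, `CT`.
#' @export
terminal_parameters <- function(network) {
  if (is.null(network$terminals)) {
    network <- derive_terminal_parameters(network)
  }
  network$terminals
}
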