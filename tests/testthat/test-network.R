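test_that("packaged equine tree loads with the documented shape", {
  net <- arterial_network(equine_segment_table())
  expect_equal(nrow(net$segments), 117)
  expect_equal(length(net$terminal_ids), 62)
  expect_equal(net$root_id, "1")
  # single rooted tree: every segment reachable, asserted at load; regions
  # assigned for every terminal
  term <- net$segments[net$segments$is_terminal, ]
  expect_true(all(term$region %in% c(
    "heart", "brain", "muscle", "kidney", "splanchnic", "other"
  )))
})

test_that("schema violations are rejected with the offending row named", {
  tab <- equine_segment_table()
  expect_error(arterial_network(tab[, -4]), "missing column")
  bad <- tab
  bad$segment_id[5] <- bad$segment_id[4]
  expect_error(arterial_network(bad), "duplicate")
  bad <- tab
  bad$parent_id[10] <- "nonexistent"
  expect_error(arterial_network(bad), "nonexistent")
  bad <- tab
  bad$length_mm[7] <- 0
  expect_error(arterial_network(bad), tab$segment_id[7])
  bad <- tab
  bad$parent_id[1] <- "2"  # root becomes child of its own subtree: cycle
  expect_error(arterial_network(bad), "root|cycle")
})

test_that("a single-segment table builds a degenerate 1-terminal network", {
  one <- tibble::tibble(
    segment_id = "1", name = "tube", parent_id = NA_character_,
    angle_1d = 0, length_mm = 100, mean_diameter_mm = 10,
    proximal_diameter_mm = 10, distal_diameter_mm = 10,
    distensibility_1e3_mmHg = 4, region = "other"
  )
  net <- arterial_network(one)
  expect_equal(length(net$terminal_ids), 1)
  # a lone 10 mm tube has Zc above the total resistance, so the R1 = Zc rule
  # must fall back to the documented clamp
  expect_warning(net <- derive_terminal_parameters(net), "clamping")
  expect_equal(net$terminals$RT, 0.14)
  expect_equal(net$terminals$R1, 0.9 * 0.14)
})

test_that("reflection coefficient follows the admittance formula", {
  expect_equal(reflection_coefficient(2, c(4, 4)), 0)   # matched junction
  expect_equal(reflection_coefficient(1, 3), 0.5)       # hand evaluation
  expect_lt(reflection_coefficient(1, rep(1e-8, 4)), -1 + 1e-6)  # open end
  expect_error(reflection_coefficient(1, numeric(0)), "daughter")
})

test_that("packaged tapered diameters keep all junction reflections below 0.2", {
  net <- apply_tapering(arterial_network(equine_segment_table()))
  expect_equal(nrow(net$junction_gamma), 55)
  expect_lt(max(abs(net$junction_gamma$gamma)), 0.2)
})

test_that("tapering optimiser fixes a deliberately mismatched junction", {
  tab <- tibble::tibble(
    segment_id = c("1", "2", "3"),
    name = c("parent", "d1", "d2"),
    parent_id = c(NA, "1", "1"),
    angle_1d = 0, length_mm = 100,
    mean_diameter_mm = c(20, 10, 10),       # 2:1 area mismatch at the split
    proximal_diameter_mm = c(20, 10, 10),   # untapered start
    distal_diameter_mm = c(20, 10, 10),
    distensibility_1e3_mmHg = 4,
    region = "other"
  )
  net0 <- arterial_network(tab)
  g0 <- junction_reflections(net0)$gamma
  expect_gt(abs(g0), 0.2)
  # wipe the taper columns so the optimiser runs from linear tapering
  tab2 <- tab
  tab2$proximal_diameter_mm <- tab2$mean_diameter_mm
  tab2$distal_diameter_mm <- tab2$mean_diameter_mm
  net1 <- suppressWarnings(apply_tapering(arterial_network(tab2)))
  g1 <- net1$junction_gamma$gamma
  expect_lt(abs(g1), abs(g0))
  expect_lt(abs(g1), 0.2)
  # mean area preserved per segment
  a_mean0 <- pi / 4 * tab$mean_diameter_mm^2
  a_mean1 <- (pi / 4 * net1$segments$proximal_diameter_mm^2 +
    pi / 4 * net1$segments$distal_diameter_mm^2) / 2
  expect_equal(a_mean1, a_mean0, tolerance = 1e-6)
})

test_that("terminal derivation honours the printed resistance and compliance totals", {
  net <- equine_network_cached()
  tp <- net$terminals
  expect_equal(1 / sum(1 / tp$RT), 0.14, tolerance = 1e-6)
  expect_true(all(tp$R1 > 0 & tp$R2 > 0 & tp$CT > 0))
  expect_equal(tp$R1 + tp$R2, tp$RT)
  cs <- net$compliance_summary
  expect_equal(sum(tp$CT) / cs$total_systemic_compliance, 0.20, tolerance = 1e-9)
  # regional conductances match the reference flow fractions
  cond <- tapply(1 / tp$RT, tp$region, sum) / sum(1 / tp$RT)
  expect_equal(
    as.numeric(cond[c("heart", "brain", "muscle", "kidney", "splanchnic", "other")]),
    c(0.05, 0.10, 0.15, 0.20, 0.30, 0.20),
    tolerance = 1e-9
  )
  # R1 equals the terminal characteristic impedance except where clamped
  term <- net$segments[net$segments$is_terminal, ]
  zc <- vapply(seq_len(nrow(term)), function(i) {
    characteristic_impedance(
      term$distal_diameter_mm[i],
      distensibility_ref = term$distensibility_1e3_mmHg[i]
    )
  }, numeric(1))
  clamped <- zc >= tp$RT[match(term$segment_id, tp$terminal_id)]
  i <- match(term$segment_id, tp$terminal_id)
  expect_equal(tp$R1[i][!clamped], zc[!clamped], tolerance = 1e-9)
  expect_equal(tp$R1[i][clamped], 0.9 * tp$RT[i][clamped], tolerance = 1e-9)
})

test_that("characteristic impedance has the stated proportionalities", {
  z1 <- characteristic_impedance(20, distensibility_ref = 4)
  z2 <- characteristic_impedance(20 * sqrt(2), distensibility_ref = 4)
  expect_equal(z2, z1 / 2, tolerance = 1e-12)  # doubling area halves Zc
  # unit round-trip: rho * PWV / A in SI converted to mmHg.s/ml
  a <- pi / 4 * 0.02^2
  pwv <- local_pwv(100, a, 4e-3)
  expect_equal(z1, 1050 * pwv / a * 1e-6 / 133.322, tolerance = 1e-12)
})

test_that("gravity projection follows the sagittal-plane convention", {
  expect_equal(gravity_projection(0), 0)     # descending aorta: neutral
  expect_equal(gravity_projection(270), 1)   # straight down: fully assisted
  expect_equal(gravity_projection(90), -1)   # straight up: fully opposed
  expect_equal(gravity_projection(180), 0, tolerance = 1e-15)
  # odd under reflection about the horizontal
  a <- c(30, 115, 240, 335)
  expect_equal(gravity_projection(360 - a), -gravity_projection(a))
})
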