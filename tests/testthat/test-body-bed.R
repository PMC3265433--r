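# small uniform toy body: n equal segments, chosen masses, one vertebra map
toy_body <- function(masses, half_width = 150, extent = 300) {
  segs <- data.frame(
    name = paste0("seg", seq_along(masses)),
    mass_kg = masses,
    extent_mm = rep(extent, length(masses)),
    half_width_mm = rep(half_width, length(masses))
  )
  body_profile(segs, name = "toy")
}

test_that("body shape classification uses the strict 1.45 threshold", {
  expect_identical(classify_body_shape(1.59), "triangular")
  expect_identical(classify_body_shape(1.52), "triangular")
  expect_identical(classify_body_shape(1.33), "square")
  expect_identical(classify_body_shape(1.28), "square")
  expect_identical(classify_body_shape(1.45), "square")
  expect_error(classify_body_shape(-1), "positive")
  presets <- anthropometric_presets()
  expect_identical(presets$shape, c("triangular", "square",
                                    "triangular", "square"))
})

test_that("build_body conserves mass, realizes the width ratio, is linear", {
  for (p in c("HTM", "HSM", "LTM", "LSM")) {
    b <- build_body(p)
    tab <- anthropometric_presets()
    row <- tab[tab$name == p, ]
    expect_equal(sum(b$segments$mass_kg), row$weight_kg, tolerance = 1e-12)
    expect_equal(sum(b$segments$extent_mm), row$height_cm * 10,
                 tolerance = 1e-12)
    sw <- b$segments$half_width_mm[b$segments$name == "shoulder"]
    pw <- b$segments$half_width_mm[b$segments$name == "pelvis"]
    expect_equal(sw / pw, row$shoulder_pelvis_ratio, tolerance = 1e-9)
  }
  # doubling weight doubles every segment mass
  b1 <- build_body(list(height_cm = 180, weight_kg = 80,
                        shoulder_pelvis_ratio = 1.5))
  b2 <- build_body(list(height_cm = 180, weight_kg = 160,
                        shoulder_pelvis_ratio = 1.5))
  expect_equal(b2$segments$mass_kg, 2 * b1$segments$mass_kg)
  # bad fraction config
  contour <- body_contour_defaults()
  contour$mass_fractions[1] <- contour$mass_fractions[1] + 0.01
  expect_error(build_body("HTM", contour), "sum to 1")
  # vertebra map: monotone, C7 at the cranial shoulder end, L5 in the
  # cranial part of the pelvis
  b <- build_body("HTM")
  vm <- b$vertebra_map
  expect_identical(names(vm), vertebra_labels())
  expect_true(all(diff(vm) > 0))
  seg <- b$segments
  expect_equal(unname(vm["C7"]), seg$start_mm[seg$name == "shoulder"])
  expect_gt(unname(vm["L5"]), seg$start_mm[seg$name == "pelvis"])
  expect_lt(unname(vm["L5"]), seg$end_mm[seg$name == "pelvis"])
  # all thoracic markers lie over the shoulder segment, lumbar over
  # waist/pelvis: the fitted thoracic line sees a single support
  expect_true(all(vm[thoracic_labels()] <=
                    seg$end_mm[seg$name == "shoulder"]))
  expect_true(all(vm[lumbar_labels()] >
                    seg$end_mm[seg$name == "shoulder"]))
})

test_that("uncoupled equilibrium is the independent spring balance", {
  # two-segment toy: 60 kg on K = 6 N/mm, 30 kg on K = 3 N/mm
  body <- toy_body(c(60, 30))
  bed <- mattress_arrangement(c(2, 1), c(300, 300))  # 3 blocks per zone
  eq <- solve_equilibrium(body, bed, coupling = 0)
  expect_equal(eq$segments$K_N_per_mm, c(6, 3))
  expect_equal(eq$segments$sag_mm, c(98.1, 98.1), tolerance = 1e-9)
  # equal half-widths + masses proportional to support -> straight spine
  contour <- body_contour_defaults()
  contour$half_widths_mm[] <- 150
  b6 <- build_body(list(height_cm = 180, weight_kg = 80,
                        shoulder_pelvis_ratio = 1), contour)
  bedu <- uniform_bed(3, b6)
  K <- spinealign:::segment_support(b6, bedu)
  b6$segments$mass_kg <- as.numeric(K) * 2   # sag = 2 g everywhere
  eq6 <- solve_equilibrium(b6, bedu, coupling = 0)
  expect_lt(diff(range(eq6$segments$height_mm)), 1e-9)
  expect_equal(compute_p8(eq6$curve)$dev_deg, 0, tolerance = 1e-9)
})

test_that("static force balance holds without saturation", {
  set.seed(81)
  for (i in 1:10) {
    body <- toy_body(runif(6, 5, 35), half_width = 200)
    bed <- mattress_arrangement(runif(6, 2, 20), body$segments$extent_mm)
    eq <- solve_equilibrium(body, bed, coupling = 0)
    lhs <- sum(eq$segments$K_N_per_mm * eq$segments$sag_mm)
    rhs <- sum(body$segments$mass_kg) * 9.81
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("the rigid limit leaves heights at the contour half-widths", {
  for (p in c("HTM", "LSM")) {
    b <- build_body(p)
    eq <- solve_equilibrium(b, uniform_bed(1e6, b), coupling = 0)
    expect_lt(max(eq$segments$sag_mm), 0.01)
    expect_equal(eq$segments$height_mm, b$segments$half_width_mm,
                 tolerance = 1e-4)
    # the narrow waist lies lowest among the spine-bearing segments:
    # the lumbar markers over the waist are the lowest spine points
    sh <- eq$spine_heights_mm
    expect_equal(unname(sh["L1"]), min(sh))
    expect_lt(unname(sh["L1"]), unname(sh["L5"]))
    expect_lt(unname(sh["L1"]), unname(sh["C7"]))
  }
})

test_that("softening a zone never lifts the segments above it", {
  set.seed(82)
  for (coupling in c(0, 0.1)) {
    body <- build_body("HSM")
    bed1 <- uniform_bed(5, body)
    eq1 <- solve_equilibrium(body, bed1, coupling = coupling)
    for (z in 1:6) {
      k <- bed1$zones$stiffness_N_per_mm
      k[z] <- 2
      bed2 <- mattress_arrangement(k, bed1$zones$extent_mm)
      eq2 <- solve_equilibrium(body, bed2, coupling = coupling)
      over <- spinealign:::segment_support(body, bed2) <
        spinealign:::segment_support(body, bed1) - 1e-12
      expect_true(all(eq2$segments$sag_mm[over] >=
                        eq1$segments$sag_mm[over] - 1e-6))
    }
  }
})

test_that("surface signatures: sagging pelvis on soft, lumbar droop on firm", {
  for (p in c("HTM", "HSM", "LTM", "LSM")) {
    b <- build_body(p)
    soft <- solve_equilibrium(b, uniform_bed(2, b))
    firm <- solve_equilibrium(b, uniform_bed(100, b))
    # C7 ends up higher than the pelvis on a soft bed
    expect_gt(unname(soft$spine_heights_mm["C7"]),
              unname(soft$spine_heights_mm["L5"]))
    # on the firm bed the lumbar spine lies below the thoracic line
    expect_lt(unname(firm$spine_heights_mm["L1"]),
              unname(firm$spine_heights_mm["C7"]))
  }
})

test_that("deviation ordering soft > firm > customized holds for every preset", {
  for (p in c("HTM", "HSM", "LTM", "LSM")) {
    b <- build_body(p)
    dev_soft <- compute_p8(solve_equilibrium(b, uniform_bed(2, b))$curve)$dev_deg
    dev_firm <- compute_p8(solve_equilibrium(b, uniform_bed(100, b))$curve)$dev_deg
    opt <- optimize_zones(b)
    expect_gt(dev_soft, dev_firm)
    expect_gt(dev_firm, opt$dev_deg)
  }
})

test_that("equilibrium validates coverage and coupling", {
  body <- toy_body(c(40, 40))
  short_bed <- mattress_arrangement(2, 300)  # covers only the first segment
  expect_error(solve_equilibrium(body, short_bed), "uncovered")
  bed <- mattress_arrangement(c(2, 2), c(300, 300))
  expect_error(solve_equilibrium(body, bed, coupling = -1),
               "non-negative")
})
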