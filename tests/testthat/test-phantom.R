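# phantom: synthetic anatomy, per-fraction deformation, observer contour
# noise (with calibration), and the conformal dose surrogate.

test_that("anatomy_params validates geometry", {
  expect_s3_class(anatomy_params(), "anatomy_params")
  expect_error(anatomy_params(ctv = list(semiaxes = c(25, 22, 28),
                                         penetration_mm = -1)))
  expect_error(anatomy_params(bowel = list(radius = 0, n_loops = 2,
                                           z_range = c(105, 130),
                                           loop_amplitude = c(22, 18),
                                           clearance_mm = 3)))
})

test_that("planning case is deterministic in the seed and seed-sensitive", {
  pc1 <- small_planning_case(seed = 5)
  pc2 <- small_planning_case(seed = 5)
  pc3 <- small_planning_case(seed = 6)
  for (nm in c("Bladder", "Bowel", "CTV"))
    expect_identical(get_structure(pc1, nm)$occupancy,
                     get_structure(pc2, nm)$occupancy)
  expect_false(identical(get_structure(pc1, "Bladder")$occupancy,
                         get_structure(pc3, "Bladder")$occupancy))
})

test_that("planning case realises the requested geometry", {
  grid <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(80, 80, 50))
  pc <- generate_planning_case(anatomy_params(seed = 7), grid)
  bl <- get_structure(pc, "Bladder"); bw <- get_structure(pc, "Bowel")
  ctv <- get_structure(pc, "CTV")
  vox_diag <- sqrt(sum(grid$spacing^2))
  # requested 10 mm penetration recovered within a voxel diagonal
  expect_lt(abs(max_penetration_mm(ctv, bl) - 10), vox_diag)
  # bladder and bowel disjoint (clearance enforced)
  expect_equal(sum(bl$occupancy & bw$occupancy), 0)
  # all structures non-trivial
  for (m in list(bl, bw, ctv)) expect_gt(volume_cc(m), 10)
})

test_that("zero penetration yields a CTV disjoint from the bladder", {
  grid <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(80, 80, 50))
  ap <- anatomy_params(ctv = list(semiaxes = c(25, 22, 28), penetration_mm = 0),
                       seed = 7)
  pc <- generate_planning_case(ap, grid)
  expect_equal(sum(get_structure(pc, "CTV")$occupancy &
                   get_structure(pc, "Bladder")$occupancy), 0)
})

test_that("anatomy that cannot fit the grid errors rather than truncating", {
  tiny <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(30, 30, 20))
  expect_error(generate_planning_case(anatomy_params(seed = 1), tiny),
               "clearance")
})

test_that("smooth_noise_field is standardized, smooth, and deterministic", {
  g <- voxel_grid(c(0, 0, 0), c(2, 2, 4), c(30, 30, 20))
  f1 <- smooth_noise_field(g, 20, seed = 5)
  f2 <- smooth_noise_field(g, 20, seed = 5)
  f3 <- smooth_noise_field(g, 20, seed = 6)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_lt(abs(mean(f1)), 1e-10)
  expect_equal(sd(f1), 1, tolerance = 1e-10)
  # smoothness: neighbouring voxels differ far less than the field SD
  expect_lt(mean(abs(diff(f1[, 15, 10]))), 0.5)
})

test_that("generate_fraction: amplitude 0 is the identity, deformation is bounded", {
  pc <- small_planning_case(seed = 2)
  id <- generate_fraction(pc, 0, seed = 1, fraction_id = "F1")
  for (nm in c("Bladder", "Bowel", "CTV"))
    expect_identical(get_structure(id, nm)$occupancy,
                     get_structure(pc, nm)$occupancy)
  fr <- generate_fraction(pc, 4, seed = 1, fraction_id = "F1")
  expect_equal(fr$fraction_id, "F1")
  for (nm in c("Bladder", "Bowel")) {
    v0 <- volume_cc(get_structure(pc, nm)); v1 <- volume_cc(get_structure(fr, nm))
    expect_lt(abs(v1 - v0) / v0, 0.3)                    # volume-change bound
    d <- dice(get_structure(pc, nm), get_structure(fr, nm))
    expect_lt(d, 1)                                      # something moved
    expect_gt(d, 0.5)                                    # but plausibly
  }
  # target deforms rigidly: voxel count preserved up to resampling jitter
  v0 <- sum(get_structure(pc, "CTV")$occupancy)
  v1 <- sum(get_structure(fr, "CTV")$occupancy)
  expect_lt(abs(v1 - v0) / v0, 0.05)
  # bladder and bowel stay disjoint after deformation
  expect_equal(sum(get_structure(fr, "Bladder")$occupancy &
                   get_structure(fr, "Bowel")$occupancy), 0)
  expect_error(generate_fraction(pc, -1, seed = 1))
})

test_that("observer noise: zero amplitude and bias reproduce truth exactly", {
  pc <- small_planning_case(seed = 4)
  prof <- observer_profile("D0", "physician", noise_amplitude_mm = 0)
  ob <- generate_observer_contours(pc, prof, seed = 3)
  expect_equal(ob$observer_id, "D0")
  for (nm in c("Bladder", "Bowel"))
    expect_identical(get_structure(ob, nm)$occupancy,
                     get_structure(pc, nm)$occupancy)
})

test_that("observer noise is deterministic, amplitude-monotone in Dice", {
  pc <- small_planning_case(seed = 4)
  mean_dice <- function(amp) {
    prof <- observer_profile("X", "student", amp)
    mean(vapply(1:6, function(r) {
      ob <- generate_observer_contours(pc, prof, seed = 50 + r,
                                       structures = "Bladder")
      dice(get_structure(pc, "Bladder"), get_structure(ob, "Bladder"))
    }, numeric(1)))
  }
  d_small <- mean_dice(0.8); d_big <- mean_dice(3)
  expect_gt(d_small, d_big)
  expect_gt(d_small, 0.9)
  ob1 <- generate_observer_contours(pc, observer_profile("X", "student", 2), 7)
  ob2 <- generate_observer_contours(pc, observer_profile("X", "student", 2), 7)
  expect_identical(get_structure(ob1, "Bladder")$occupancy,
                   get_structure(ob2, "Bladder")$occupancy)
})

test_that("a positive contouring bias systematically inflates volume", {
  pc <- small_planning_case(seed = 4)
  # bias must exceed the coarse 3-4 mm voxel pitch to flip any voxel
  over <- observer_profile("O+", "student", 0, bias_mm = 4)
  under <- observer_profile("O-", "student", 0, bias_mm = -4)
  vo <- volume_cc(get_structure(generate_observer_contours(pc, over, 1), "Bladder"))
  vu <- volume_cc(get_structure(generate_observer_contours(pc, under, 1), "Bladder"))
  vt <- volume_cc(get_structure(pc, "Bladder"))
  expect_gt(vo, vt)
  expect_lt(vu, vt)
})

test_that("observer_profile validates its arguments", {
  expect_error(observer_profile("X", "surgeon"))
  expect_error(observer_profile("X", "student", -1))
  expect_error(observer_profile("X", "student", 1, corr_len_mm = 0))
})

test_that("dose surrogate: geometry, normalisation, caps, determinism", {
  pc <- small_planning_case(seed = 8)
  b <- apply_planning_rules(pc)
  ptv <- get_structure(b, "PTV")
  par <- dose_model_params(50, seed = 5)
  d <- synthesize_dose(ptv, par)
  expect_identical(d$values, synthesize_dose(ptv, par)$values)
  expect_true(all(d$values >= 0))
  # PTV median normalised to prescription
  expect_equal(median(d$values[ptv$occupancy]), 50, tolerance = 1e-9)
  # dose falls off away from the PTV
  far <- signed_distance(ptv) > 25
  expect_lt(max(d$values[far]), 10)
  # an organ cap clamps exactly
  organ <- get_structure(b, "Bowel_eval")
  dc <- synthesize_dose(ptv, par, list(list(mask = organ, cap_gy = 30)))
  expect_lte(max(dc$values[organ$occupancy]), 30)
  expect_identical(dc$values[!organ$occupancy], d$values[!organ$occupancy])
  # conformity grows with the bulge parameter
  # bulge steps of >= one voxel pitch so the isodose moves on this coarse grid
  ci <- vapply(c(0, 4, 8), function(bu)
    conformity_index(synthesize_dose(
      ptv, dose_model_params(50, bulge_mm = bu, hotspot_frac = 0)), ptv, 50),
    numeric(1))
  expect_true(all(diff(ci) > 0))
  expect_equal(ci[1], 1)           # no bulge, no noise: perfectly conformal
  expect_error(synthesize_dose(structure_mask(ptv$grid), par), "empty")
  expect_error(dose_model_params(0))
  expect_error(dose_model_params(50, falloff_mm = 0))
})

test_that("noise calibration recovers the expected Dice (coarse phantom)", {
  pc <- small_planning_case(seed = 10)
  cal <- calibrate_observer_noise(pc, "Bladder", target_dice = 0.95,
                                  n_rep = 8, seed = 2, tol = 0.005)
  expect_gt(cal$amplitude_mm, 0)
  expect_lt(abs(cal$achieved_dice - 0.95), 0.02)
  prof <- observer_profile("C", "therapist", cal$amplitude_mm)
  dd <- vapply(1:20, function(r) {
    ob <- generate_observer_contours(pc, prof, seed = 900 + r,
                                     structures = "Bladder")
    dice(get_structure(pc, "Bladder"), get_structure(ob, "Bladder"))
  }, numeric(1))
  expect_lt(abs(mean(dd) - 0.95), 0.02)
})
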