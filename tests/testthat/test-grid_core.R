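# grid_core: voxel grids, masks, set algebra, distance transforms,
# expansion, depth trimming, cranial crop, rasterization.

test_that("voxel_grid validates its inputs and computes voxel volume", {
  g <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(10, 12, 8))
  expect_s3_class(g, "voxel_grid")
  expect_equal(voxel_volume_cc(g), 1.5 * 1.5 * 3 / 1000)
  expect_error(voxel_grid(c(0, 0), c(1, 1, 1), c(5, 5, 5)))
  expect_error(voxel_grid(c(0, 0, 0), c(0, 1, 1), c(5, 5, 5)))
  expect_error(voxel_grid(c(0, 0, 0), c(1, 1, 1), c(0, 5, 5)))
  expect_error(voxel_grid(c(0, 0, 0), c(1, 1, 1), c(5.5, 5, 5)))
})

test_that("axis coordinates use voxel-centre semantics", {
  g <- voxel_grid(c(10, 20, 30), c(2, 3, 4), c(3, 3, 3))
  expect_equal(axis_coords(g, 1), c(10, 12, 14))
  expect_equal(axis_coords(g, 2), c(20, 23, 26))
  expect_equal(axis_coords(g, 3), c(30, 34, 38))
})

test_that("grid compatibility is exact equality of origin, spacing, shape", {
  g1 <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(5, 5, 5))
  g2 <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(5, 5, 5))
  g3 <- voxel_grid(c(0, 0, 1e-9), c(1, 1, 2), c(5, 5, 5))
  g4 <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(5, 5, 6))
  expect_true(grids_compatible(g1, g2))
  expect_false(grids_compatible(g1, g3))
  expect_false(grids_compatible(g1, g4))
  expect_error(stop_if_incompatible(g1, g3), "incompatible")
  expect_silent(stop_if_incompatible(g1, g2))
})

test_that("structure_mask validates shape and records role and provenance", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4))
  m <- structure_mask(g, array(TRUE, c(4, 4, 4)), name = "B", role = "OAR")
  expect_equal(volume_cc(m), 64 / 1000)
  expect_error(structure_mask(g, array(TRUE, c(4, 4, 5))))
  expect_error(structure_mask(g, array(NA, c(4, 4, 4))))
  expect_error(structure_mask(g, array(TRUE, c(4, 4, 4)), role = "WRONG"))
})

test_that("mask set algebra matches logical operations (property)", {
  set.seed(11)
  for (r in 1:200) {
    g <- random_grid(c(5, 4, 3))
    a <- random_mask(g, 0.4); b <- random_mask(g, 0.4)
    expect_identical(mask_union(a, b)$occupancy, a$occupancy | b$occupancy)
    expect_identical(mask_intersect(a, b)$occupancy, a$occupancy & b$occupancy)
    expect_identical(mask_diff(a, b)$occupancy, a$occupancy & !b$occupancy)
    # algebraic identities
    expect_identical(mask_union(a, b)$occupancy, mask_union(b, a)$occupancy)
    expect_identical(
      mask_diff(a, b)$occupancy,
      mask_diff(mask_union(a, b), b)$occupancy)
  }
})

test_that("set operations on incompatible grids error", {
  g1 <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4))
  g2 <- voxel_grid(c(1, 0, 0), c(1, 1, 1), c(4, 4, 4))
  a <- structure_mask(g1, array(TRUE, c(4, 4, 4)))
  b <- structure_mask(g2, array(TRUE, c(4, 4, 4)))
  expect_error(mask_union(a, b), "incompatible")
})

test_that("distance_map equals the brute-force oracle (property, anisotropic)", {
  set.seed(21)
  for (r in 1:25) {
    g <- random_grid(c(9, 8, 6))
    m <- random_mask(g, 0.08)
    dm <- distance_map(m)
    bf <- oracle_distance_map(m$occupancy, g$spacing)
    if (any(m$occupancy)) {
      expect_lt(max(abs(dm - bf)), 1e-9)
    } else {
      expect_true(all(is.infinite(dm)))
    }
  }
})

test_that("expand_mask: identity at 0, error below 0, exact small case", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(11, 11, 11))
  m <- box_mask(g, 6, 6, 6)
  expect_identical(expand_mask(m, 0)$occupancy, m$occupancy)
  expect_error(expand_mask(m, -1))
  # all voxel centres within 3 mm of the centre voxel: 123 on a unit grid
  expect_equal(sum(expand_mask(m, 3)$occupancy), 123)
})

test_that("expand_mask matches thresholded oracle distance (property)", {
  set.seed(31)
  for (r in 1:25) {
    g <- random_grid(c(8, 7, 6))
    m <- random_mask(g, 0.1)
    if (!any(m$occupancy)) next
    mar <- runif(1, 0, 5)
    e <- expand_mask(m, mar)
    bf <- oracle_distance_map(m$occupancy, g$spacing) <= mar
    expect_identical(e$occupancy, bf)
  }
})

test_that("expand_mask is monotone and inclusive at the boundary", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(15, 15, 15))
  m <- box_mask(g, 8, 8, 8)
  e2 <- expand_mask(m, 2); e3 <- expand_mask(m, 3)
  expect_true(all(e3$occupancy[e2$occupancy]))      # monotone in margin
  # boundary inclusive: a voxel exactly margin away is included
  expect_true(expand_mask(m, 2)$occupancy[10, 8, 8])
  expect_false(expand_mask(m, 1.999)$occupancy[10, 8, 8])
})

test_that("expanded sphere volume approximates the analytic volume", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(60, 60, 60))
  xs <- axis_coords(g, 1)
  occ <- outer(outer((xs - 30)^2, (xs - 30)^2, "+"), (xs - 30)^2, "+") <= 400
  e <- expand_mask(structure_mask(g, occ), 3)
  vol_mm3 <- volume_cc(e) * 1000
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 23^3) / (4 / 3 * pi * 23^3), 0.05)
})

test_that("depth_map is the oracle distance to the complement", {
  set.seed(41)
  for (r in 1:10) {
    g <- random_grid(c(8, 7, 6))
    m <- random_mask(g, 0.5)
    if (!any(m$occupancy) || all(m$occupancy)) next
    dep <- depth_map(m)
    bf <- oracle_distance_map(!m$occupancy, g$spacing)
    expect_lt(max(abs(dep[m$occupancy] - bf[m$occupancy])), 1e-9)
    expect_true(all(dep[!m$occupancy] == 0))
  }
})

test_that("trim_to_depth limits penetration and 0-depth equals subtraction", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(30, 30, 10))
  occ_org <- array(FALSE, c(30, 30, 10)); occ_org[, 11:30, ] <- TRUE
  occ_tgt <- array(FALSE, c(30, 30, 10)); occ_tgt[10:20, 1:21, ] <- TRUE
  org <- structure_mask(g, occ_org); tgt <- structure_mask(g, occ_tgt)
  tr <- trim_to_depth(tgt, org, 3)
  expect_lte(max_penetration_mm(tr, org), 3)
  expect_true(all(tgt$occupancy[tr$occupancy]))      # subset of target
  expect_identical(trim_to_depth(tgt, org, 0)$occupancy,
                   mask_diff(tgt, org)$occupancy)
  expect_error(trim_to_depth(tgt, org, -1))
})

test_that("max_penetration_mm is 0 for disjoint masks", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(10, 10, 5))
  a <- box_mask(g, 1:3, 1:3, 1:2)
  b <- box_mask(g, 7:9, 7:9, 4:5)
  expect_equal(max_penetration_mm(a, b), 0)
})

test_that("crop_above removes voxels with centre z above the limit", {
  g <- voxel_grid(c(0, 0, 10), c(1, 1, 2), c(4, 4, 6))  # z centres 10..20
  m <- structure_mask(g, array(TRUE, c(4, 4, 6)))
  cr <- crop_above(m, 14)
  kept_z <- axis_coords(g, 3)[apply(cr$occupancy, 3, any)]
  expect_true(all(kept_z <= 14))
  expect_equal(sum(cr$occupancy), 4 * 4 * 3)
  # inclusive boundary: centre exactly at the limit is kept
  expect_true(any(cr$occupancy[, , 3]))
})

test_that("rasterize fills a square exactly and respects even-odd holes", {
  g <- voxel_grid(c(0.5, 0.5, 0), c(1, 1, 3), c(20, 20, 3))
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  ps <- slice_polygon_set("sq", list(list(z = 0, xy = sq)))
  m <- rasterize(ps, g)
  expect_equal(sum(m$occupancy), 100)
  expect_equal(volume_cc(m), 100 * 3 / 1000)
  hole <- rbind(c(3, 3), c(7, 3), c(7, 7), c(3, 7))
  ps2 <- slice_polygon_set("h", list(list(z = 0, xy = sq),
                                     list(z = 0, xy = hole)))
  expect_equal(sum(rasterize(ps2, g)$occupancy), 100 - 16)
})

test_that("rasterize matches the point-in-polygon oracle on random polygons", {
  set.seed(51)
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(15, 15, 1))
  for (r in 1:30) {
    # random star-shaped polygon around (7, 7)
    nv <- sample(3:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 6.5)
    poly <- cbind(7 + rad * cos(ang), 7 + rad * sin(ang))
    m <- rasterize(slice_polygon_set("p", list(list(z = 0, xy = poly))), g)
    for (i in 1:15) for (j in 1:15) {
      expect_identical(m$occupancy[i, j, 1],
                       oracle_point_in_polygon(i - 1, j - 1, poly))
    }
  }
})

test_that("rasterize rejects polygons off the slice lattice and bad input", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 3), c(5, 5, 3))  # z centres 0, 3, 6
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2))
  expect_error(
    rasterize(slice_polygon_set("p", list(list(z = 1.8, xy = sq))), g),
    "1.8")
  expect_error(slice_polygon_set("p", list(list(z = 0, xy = sq[1:2, ]))))
  expect_error(slice_polygon_set("p", list(list(z = NaN, xy = sq))))
})

test_that("print methods produce output and return invisibly", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3))
  m <- box_mask(g, 2, 2, 2)
  expect_output(print(g), "voxel_grid")
  expect_output(print(m), "box")
})
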