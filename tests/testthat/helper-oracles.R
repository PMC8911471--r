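# Independent brute-force oracles and small fixture helpers.  Everything
# here is deliberately naive (O(n^2) scans, no shared code with the
# package internals) so agreement is meaningful.

# exact distance-to-set by exhaustive pairwise search (voxel centres, mm)
oracle_distance_map <- function(occ, spacing) {
  d <- dim(occ)
  xs <- (seq_len(d[1]) - 1) * spacing[1]
  ys <- (seq_len(d[2]) - 1) * spacing[2]
  zs <- (seq_len(d[3]) - 1) * spacing[3]
  pts <- which(occ, arr.ind = TRUE)
  out <- array(Inf, dim = d)
  if (nrow(pts) == 0) return(out)
  px <- xs[pts[, 1]]; py <- ys[pts[, 2]]; pz <- zs[pts[, 3]]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- sqrt(min((xs[i] - px)^2 + (ys[j] - py)^2 + (zs[k] - pz)^2))
  out
}

# Dice from first principles on logical arrays
oracle_dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# D(v_cc): walk the descending dose list accumulating volume; the dose at
# cumulative volume v is interpolated between the voxels whose half-open
# volume intervals bracket v (voxel k covers ((k-0.5)vv, (k+0.5)vv])
oracle_dose_at_volume <- function(doses, vv, v) {
  d <- sort(doses, decreasing = TRUE)
  k <- v / vv + 0.5
  if (k <= 1) return(d[1])
  if (k >= length(d)) return(d[length(d)])
  k0 <- floor(k)
  d[k0] + (k - k0) * (d[k0 + 1] - d[k0])
}

# RTOG conformity index by direct voxel counting over the whole grid
oracle_ci <- function(dose_vals, ptv_occ, rx, vv) {
  sum(dose_vals >= 0.95 * rx) * vv / (sum(ptv_occ) * vv)
}

# point-in-polygon by ray casting with the same half-open edge rule the
# DICOM rasterizer community uses; counts crossings strictly right of the
# point
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi <= y && yj > y) || (yj <= y && yi > y)) {
      xcross <- poly[i, 1] + (y - yi) / (yj - yi) * (poly[j, 1] - poly[i, 1])
      if (xcross > x) inside <- !inside
    }
    j <- i
  }
  inside
}

# random small test grid (anisotropic, non-zero origin)
random_grid <- function(shape = c(8, 7, 5)) {
  voxel_grid(origin = runif(3, -20, 20),
             spacing = c(runif(2, 0.8, 2.5), runif(1, 1, 4)),
             shape = shape)
}

random_mask <- function(grid, p = 0.2, name = "m", role = "OAR") {
  structure_mask(grid, array(runif(prod(grid$shape)) < p, dim = grid$shape),
                 name = name, role = role)
}

# a small solid box mask
box_mask <- function(grid, i, j, k, name = "box", role = "OAR") {
  occ <- array(FALSE, grid$shape)
  occ[i, j, k] <- TRUE
  structure_mask(grid, occ, name = name, role = role)
}

# tiny complete phantom on a coarse grid for fast pipeline tests
small_planning_case <- function(seed = 1) {
  g <- voxel_grid(c(0, 0, 0), c(3, 3, 4), c(40, 40, 38))
  ap <- anatomy_params(seed = seed, jitter_frac = 0.06)
  generate_planning_case(ap, g, patient_id = sprintf("SP%d", seed))
}

# constructed fraction_outcome with given tiers
mk_outcome <- function(ct, gt, class = "therapist", id = "X",
                       patient = "P", fraction = "F1") {
  fraction_outcome(patient, fraction, id, ct, gt, observer_class = class)
}
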