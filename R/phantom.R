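# Synthetic pelvic phantom: planning anatomy (bladder, bowel loops, CTV),
# per-fraction anatomical variation, per-observer contour noise with a
# controllable expected Dice index, and a conformal dose surrogate.
#
# Noise and deformation are built from smooth Gaussian random fields
# (white noise on a coarse lattice at the correlation length, trilinearly
# interpolated to the voxel grid and standardised), applied to the signed
# distance function of a structure.  This produces realistic smooth over-
# and under-contouring rather than voxel-level salt-and-pepper noise.
# Every stochastic step draws from a seed derived from (seed, labels) so
# adding a structure or observer never perturbs the others.

## ----------------------------------------------------------- random fields

# trilinear interpolation of a 3D array at fractional (1-based) indices
trilinear_at <- function(arr, ui, vi, wi) {
  d <- dim(arr)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ui <- clamp(ui, 1, d[1]); vi <- clamp(vi, 1, d[2]); wi <- clamp(wi, 1, d[3])
  i0 <- clamp(floor(ui), 1, d[1] - 1); fx <- ui - i0
  j0 <- clamp(floor(vi), 1, d[2] - 1); fy <- vi - j0
  k0 <- clamp(floor(wi), 1, d[3] - 1); fz <- wi - k0
  idx <- function(i, j, k) i + d[1] * ((j - 1) + d[2] * (k - 1))
  a <- arr
  dim(a) <- NULL
  v000 <- a[idx(i0,     j0,     k0)]
  v100 <- a[idx(i0 + 1, j0,     k0)]
  v010 <- a[idx(i0,     j0 + 1, k0)]
  v110 <- a[idx(i0 + 1, j0 + 1, k0)]
  v001 <- a[idx(i0,     j0,     k0 + 1)]
  v101 <- a[idx(i0 + 1, j0,     k0 + 1)]
  v011 <- a[idx(i0,     j0 + 1, k0 + 1)]
  v111 <- a[idx(i0 + 1, j0 + 1, k0 + 1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# smooth zero-mean unit-variance Gaussian random field on a voxel grid with
# correlation length ~ corr_len_mm
smooth_noise_field <- function(grid, corr_len_mm, seed) {
  stopifnot(corr_len_mm > 0)
  extent <- grid$spacing * grid$shape
  nc <- pmax(ceiling(extent / corr_len_mm) + 2L, 3L)
  coarse <- with_seed(seed, array(rnorm(prod(nc)), dim = nc))
  # fractional coarse-lattice indices of each voxel centre per axis
  fr <- lapply(1:3, function(ax) {
    (axis_coords(grid, ax) - grid$origin[ax]) / corr_len_mm + 2
  })
  ui <- rep(fr[[1]], times = grid$shape[2] * grid$shape[3])
  vi <- rep(rep(fr[[2]], each = grid$shape[1]), times = grid$shape[3])
  wi <- rep(fr[[3]], each = grid$shape[1] * grid$shape[2])
  f <- trilinear_at(coarse, ui, vi, wi)
  f <- (f - mean(f)) / max(sd(f), 1e-12)
  dim(f) <- grid$shape
  f
}

#' Signed distance function of a mask
#'
#' Negative inside (minus the depth to the nearest exterior voxel centre),
#' positive outside (distance to the nearest set voxel centre), in mm.
#' Thresholding the result at 0 recovers the mask exactly.
#' @param mask a [structure_mask].
#' @return numeric array (mm).
#' @export
signed_distance <- function(mask) {
  d <- distance_map(mask)
  dep <- depth_map(mask)
  d[mask$occupancy] <- -dep[mask$occupancy]
  d
}

# perturb a structure by thresholding its SDF at a smooth noise field:
# amplitude = 0 and bias = 0 reproduce the input exactly
perturb_sdf <- function(sdf, grid, amplitude_mm, corr_len_mm, bias_mm, seed) {
  if (amplitude_mm < 0) stop("noise amplitude must be >= 0")
  thr <- bias_mm
  if (amplitude_mm > 0)
    thr <- thr + amplitude_mm * smooth_noise_field(grid, corr_len_mm, seed)
  sdf <= thr
}

## -------------------------------------------------------------- parameters

#' Phantom anatomy parameters
#'
#' Describes a pelvic planning state: a comfortably full bladder
#' (ellipsoid), loops of bowel (a tube around a helical path superior to
#' the target), and a CTV (ellipsoid) placed to penetrate the bladder to a
#' prescribed depth — emulating a low-pelvis target contoured to extend
#' into the bladder.  With the same parameters and seed the generated masks
#' are bit-identical.
#'
#' @param bladder list: `centre` (mm), `semiaxes` (mm), `filling` (scale
#'   factor on the semi-axes).
#' @param bowel list: `radius` (mm), `n_loops`, `z_range` (mm), `loop_amplitude`
#'   (x/y loop radii, mm), `clearance_mm` (minimum gap kept to the bladder).
#' @param ctv list: `semiaxes` (mm), `penetration_mm` (prescribed maximum
#'   depth into the bladder, >= 0).
#' @param jitter_frac relative jitter applied to sizes/positions under
#'   `seed` (patient-to-patient variation).
#' @param seed integer reproducibility seed.
#' @return an object of class `anatomy_params`.
#' @export
anatomy_params <- function(bladder = list(centre = c(60, 80, 75),
                                          semiaxes = c(30, 25, 22),
                                          filling = 1),
                           bowel = list(radius = 10, n_loops = 2,
                                        z_range = c(105, 130),
                                        loop_amplitude = c(22, 18),
                                        clearance_mm = 3),
                           ctv = list(semiaxes = c(25, 22, 28),
                                      penetration_mm = 10),
                           jitter_frac = 0, seed = 1) {
  bladder$filling <- bladder$filling %||% 1
  if (any(bladder$semiaxes <= 0) || any(ctv$semiaxes <= 0) || bowel$radius <= 0)
    stop("all semi-axes and radii must be > 0")
  if (ctv$penetration_mm < 0) stop("penetration depth must be >= 0")
  structure(list(bladder = bladder, bowel = bowel, ctv = ctv,
                 jitter_frac = jitter_frac, seed = as.integer(seed)),
            class = "anatomy_params")
}

ellipsoid_occ <- function(grid, centre, semi) {
  tx <- ((axis_coords(grid, 1) - centre[1]) / semi[1])^2
  ty <- ((axis_coords(grid, 2) - centre[2]) / semi[2])^2
  tz <- ((axis_coords(grid, 3) - centre[3]) / semi[3])^2
  outer(outer(tx, ty, "+"), tz, "+") <= 1
}

## ---------------------------------------------------------- planning case

#' Generate a planning-state phantom bundle
#'
#' Builds bladder, bowel and CTV masks on `grid`.  The CTV is placed so its
#' anterior tip lies `penetration_mm` deep to the posterior bladder surface
#' along the bladder normal, so the measured maximum penetration equals the
#' request to within a voxel diagonal; with `penetration_mm = 0` the CTV
#' and bladder are disjoint.  Bowel and bladder are kept disjoint with a
#' configurable clearance; bowel may overlap the CTV (as in real pelvic
#' anatomy — the Boolean rules, not the anatomy, separate them).  All
#' structures must fit in the grid with 5 mm clearance.
#'
#' @param params an [anatomy_params].
#' @param grid a [voxel_grid].
#' @param patient_id identifier for the bundle.
#' @return a [fraction_bundle] with structures `Bladder`, `Bowel`, `CTV`
#'   (fraction id `"plan"`, observer id `"truth"`).
#' @export
generate_planning_case <- function(params, grid, patient_id = "P0") {
  stopifnot(inherits(params, "anatomy_params"), inherits(grid, "voxel_grid"))
  p <- params
  jit <- function(x, scale, label) {
    if (p$jitter_frac == 0) return(x)
    with_seed(derive_seed(p$seed, "jitter", label),
              x * (1 + runif(length(x), -p$jitter_frac, p$jitter_frac) * scale))
  }
  bl_semi <- jit(p$bladder$semiaxes * p$bladder$filling, 1, "bladder_semi")
  bl_c <- p$bladder$centre
  ctv_semi <- jit(p$ctv$semiaxes, 1, "ctv_semi")
  t_pen <- p$ctv$penetration_mm

  # CTV centre: anterior tip reaches t_pen beyond the posterior bladder
  # surface, measured along -y at the CTV's (x, z)
  ctv_cx <- bl_c[1]
  ctv_cz <- jit(bl_c[3] + 3, 1, "ctv_z")
  rad <- 1 - ((ctv_cx - bl_c[1]) / bl_semi[1])^2 -
    ((ctv_cz - bl_c[3]) / bl_semi[3])^2
  if (rad <= 0) stop("CTV is laterally outside the bladder; cannot place penetration")
  y_surf <- bl_c[2] - bl_semi[2] * sqrt(rad)
  ctv_c <- c(ctv_cx, y_surf + t_pen - ctv_semi[2], ctv_cz)

  bladder_occ <- ellipsoid_occ(grid, bl_c, bl_semi)
  ctv_occ <- ellipsoid_occ(grid, ctv_c, ctv_semi)
  if (t_pen == 0) ctv_occ <- ctv_occ & !bladder_occ

  # bowel: tube around a helical path superior/anterior to the target
  bw <- p$bowel
  zr <- bw$z_range
  amp <- jit(bw$loop_amplitude, 1, "bowel_amp")
  tt <- seq(0, 1, length.out = 400)
  theta <- 2 * pi * bw$n_loops * tt
  px <- bl_c[1] + amp[1] * sin(theta)
  py <- bl_c[2] - 18 + amp[2] * cos(theta)
  pz <- zr[1] + (zr[2] - zr[1]) * tt
  path_occ <- array(FALSE, dim = grid$shape)
  ix <- pmin(pmax(round((px - grid$origin[1]) / grid$spacing[1]) + 1, 1), grid$shape[1])
  iy <- pmin(pmax(round((py - grid$origin[2]) / grid$spacing[2]) + 1, 1), grid$shape[2])
  iz <- pmin(pmax(round((pz - grid$origin[3]) / grid$spacing[3]) + 1, 1), grid$shape[3])
  path_occ[cbind(ix, iy, iz)] <- TRUE
  path_mask <- structure_mask(grid, path_occ, "bowel_path", "DERIVED")
  bowel_occ <- distance_map(path_mask) <= bw$radius
  # enforce bladder clearance
  bl_mask <- structure_mask(grid, bladder_occ, "Bladder", "OAR")
  bowel_occ <- bowel_occ & !(distance_map(bl_mask) <= bw$clearance_mm)

  # fit check: nothing within 5 mm of the grid boundary
  fit_check <- function(occ, name) {
    mi <- ceiling(5 / grid$spacing)
    d <- grid$shape
    edge <- any(occ[seq_len(min(mi[1], d[1])), , ]) ||
      any(occ[(d[1] - mi[1] + 1):d[1], , ]) ||
      any(occ[, seq_len(min(mi[2], d[2])), ]) ||
      any(occ[, (d[2] - mi[2] + 1):d[2], ]) ||
      any(occ[, , seq_len(min(mi[3], d[3]))]) ||
      any(occ[, , (d[3] - mi[3] + 1):d[3]])
    if (edge) stop("structure '", name,
                   "' exceeds the grid (needs 5 mm clearance); enlarge the grid")
  }
  fit_check(bladder_occ, "Bladder")
  fit_check(bowel_occ, "Bowel")
  fit_check(ctv_occ, "CTV")

  fraction_bundle(
    grid,
    list(Bladder = bl_mask,
         Bowel = structure_mask(grid, bowel_occ, "Bowel", "OAR"),
         CTV = structure_mask(grid, ctv_occ, "CTV", "TARGET")),
    patient_id = patient_id, fraction_id = "plan", observer_id = "truth")
}

## ------------------------------------------------------ daily deformation

#' Generate a daily-fraction anatomy from a planning bundle
#'
#' Organs at risk (bladder, bowel) are deformed by a smooth random
#' displacement field (band-limited via the correlation length); the
#' per-organ volume change is kept within `max_volume_change` by scaling
#' the field down if necessary.  The CTV is copied rigidly, unedited, as on
#' a daily positioning scan.  Deformed bladder and bowel remain disjoint
#' (contested voxels go to the organ whose warped interior is deeper).
#'
#' @param planning a planning [fraction_bundle] (from
#'   [generate_planning_case()]).
#' @param deformation_amplitude_mm RMS displacement magnitude in mm (>= 0;
#'   0 reproduces the planning anatomy exactly).
#' @param seed integer seed.
#' @param fraction_id identifier for the new fraction.
#' @param corr_len_mm correlation length of the displacement field (mm).
#' @param max_volume_change maximum allowed relative volume change per
#'   organ (default 0.3).
#' @return a [fraction_bundle] (observer id `"truth"`).
#' @export
generate_fraction <- function(planning, deformation_amplitude_mm, seed,
                              fraction_id = "F1", corr_len_mm = 30,
                              max_volume_change = 0.3) {
  stopifnot(inherits(planning, "fraction_bundle"))
  if (deformation_amplitude_mm < 0) stop("deformation amplitude must be >= 0")
  grid <- planning$grid
  out <- planning
  out$fraction_id <- fraction_id
  out$observer_id <- "truth"
  if (deformation_amplitude_mm == 0) return(out)

  comp_sd <- deformation_amplitude_mm / sqrt(3)
  u <- lapply(c("ux", "uy", "uz"), function(lbl)
    comp_sd * smooth_noise_field(grid, corr_len_mm, derive_seed(seed, lbl)))
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  gx <- rep(xs, times = ny * nz)
  gy <- rep(rep(ys, each = nx), times = nz)
  gz <- rep(zs, each = nx * ny)

  warp_one <- function(sdfv, scale) {
    ui <- (gx + scale * as.vector(u[[1]]) - grid$origin[1]) / grid$spacing[1] + 1
    vi <- (gy + scale * as.vector(u[[2]]) - grid$origin[2]) / grid$spacing[2] + 1
    wi <- (gz + scale * as.vector(u[[3]]) - grid$origin[3]) / grid$spacing[3] + 1
    w <- trilinear_at(sdfv, ui, vi, wi)
    dim(w) <- grid$shape
    w
  }

  organs <- intersect(c("Bladder", "Bowel"), names(planning$structures))
  sdfs <- lapply(organs, function(nm) signed_distance(planning$structures[[nm]]))
  names(sdfs) <- organs
  scale <- 1
  for (iter in 1:8) {
    warped <- lapply(sdfs, warp_one, scale = scale)
    ok <- TRUE
    for (nm in organs) {
      v0 <- sum(planning$structures[[nm]]$occupancy)
      v1 <- sum(warped[[nm]] <= 0)
      if (v0 > 0 && abs(v1 - v0) / v0 > max_volume_change) ok <- FALSE
    }
    if (ok) break
    scale <- scale * 0.7
  }
  occs <- lapply(warped, function(w) w <= 0)
  if (all(c("Bladder", "Bowel") %in% organs)) {
    contested <- occs$Bladder & occs$Bowel
    if (any(contested)) {
      give_bladder <- warped$Bladder[contested] <= warped$Bowel[contested]
      occs$Bladder[contested] <- give_bladder
      occs$Bowel[contested] <- !give_bladder
    }
  }
  for (nm in organs)
    out$structures[[nm]] <- structure_mask(grid, occs[[nm]], nm, "OAR")
  out
}

## ------------------------------------------------------- observer contours

#' Observer contouring profile
#'
#' Models one participant's contouring behaviour as a Gaussian random field
#' on the structure's signed distance function: `noise_amplitude_mm`
#' controls random boundary excursions (expected Dice decreases
#' monotonically with it), `bias_mm` a systematic over- (+) or under- (-)
#' contouring margin.  Zero amplitude and zero bias reproduce the reference
#' contour exactly.
#' @param id observer identifier (e.g. `"T1"`).
#' @param class observer class: `"physician"`, `"therapist"` or
#'   `"student"`.
#' @param noise_amplitude_mm boundary-noise amplitude (mm, >= 0).
#' @param corr_len_mm boundary-noise correlation length (mm, default 10).
#' @param bias_mm systematic margin bias (mm).
#' @param seed_offset integer mixed into every seed derivation for this
#'   observer.
#' @return an object of class `observer_profile`.
#' @export
observer_profile <- function(id, class = c("therapist", "physician", "student"),
                             noise_amplitude_mm = 1, corr_len_mm = 10,
                             bias_mm = 0, seed_offset = 0) {
  class <- match.arg(class)
  if (noise_amplitude_mm < 0) stop("noise amplitude must be >= 0")
  if (corr_len_mm <= 0) stop("correlation length must be > 0")
  structure(list(id = as.character(id), class = class,
                 noise_amplitude_mm = noise_amplitude_mm,
                 corr_len_mm = corr_len_mm, bias_mm = bias_mm,
                 seed_offset = as.integer(seed_offset)),
            class = "observer_profile")
}

#' Generate one observer's contours for a fraction
#'
#' Perturbs the requested structures of the truth bundle according to the
#' observer's profile (independent noise field per structure); all other
#' structures — in particular the rigidly copied CTV — are passed through
#' unchanged.  With a zero-noise, zero-bias profile the output equals the
#' truth exactly (Dice 1).
#' @param truth a truth [fraction_bundle].
#' @param profile an [observer_profile].
#' @param seed integer seed (combined with the profile's `seed_offset` and
#'   the structure name per structure).
#' @param structures structures the observer edits (default bladder and
#'   bowel); requesting a structure absent from `truth` is an error.
#' @return a [fraction_bundle] with `observer_id = profile$id`.
#' @export
generate_observer_contours <- function(truth, profile, seed,
                                       structures = c("Bladder", "Bowel")) {
  stopifnot(inherits(truth, "fraction_bundle"), inherits(profile, "observer_profile"))
  out <- truth
  out$observer_id <- profile$id
  for (nm in structures) {
    s <- get_structure(truth, nm)
    occ <- perturb_sdf(signed_distance(s), truth$grid,
                       profile$noise_amplitude_mm, profile$corr_len_mm,
                       profile$bias_mm,
                       derive_seed(seed, profile$id, profile$seed_offset, nm))
    out$structures[[s$name]] <- structure_mask(truth$grid, occ, s$name, s$role)
  }
  out
}

#' Calibrate observer-noise amplitude to an expected Dice index
#'
#' Monte-Carlo bisection: mean Dice against the reference contour is a
#' monotone decreasing function of the noise amplitude; the routine finds
#' the amplitude whose mean Dice over `n_rep` replicates matches
#' `target_dice`.
#' @param truth a truth [fraction_bundle].
#' @param structure structure name to calibrate on.
#' @param target_dice desired expected Dice in (0, 1).
#' @param corr_len_mm noise correlation length (mm).
#' @param n_rep Monte-Carlo replicates per bisection step.
#' @param seed integer seed.
#' @param lower,upper amplitude bracket (mm).
#' @param tol convergence tolerance on mean Dice.
#' @param max_iter maximum bisection steps.
#' @return list with `amplitude_mm` and `achieved_dice`.
#' @export
calibrate_observer_noise <- function(truth, structure = "Bladder",
                                     target_dice = 0.97, corr_len_mm = 10,
                                     n_rep = 24, seed = 1,
                                     lower = 0.02, upper = 10,
                                     tol = 0.002, max_iter = 14) {
  stopifnot(target_dice > 0, target_dice < 1)
  s <- get_structure(truth, structure)
  sdf <- signed_distance(s)
  mean_dice <- function(a) {
    mean(vapply(seq_len(n_rep), function(r) {
      occ <- perturb_sdf(sdf, truth$grid, a, corr_len_mm, 0,
                         derive_seed(seed, "calibrate", r))
      test <- structure_mask(truth$grid, occ, "test", "DERIVED")
      dice(s, test)
    }, numeric(1)))
  }
  f_lo <- mean_dice(lower); f_hi <- mean_dice(upper)
  if (target_dice > f_lo)
    stop(sprintf("target Dice %.3f above what amplitude %.2g mm yields (%.4f)",
                 target_dice, lower, f_lo))
  if (target_dice < f_hi)
    stop(sprintf("target Dice %.3f below what amplitude %.2g mm yields (%.4f)",
                 target_dice, upper, f_hi))
  a_lo <- lower; a_hi <- upper; a_mid <- NA; f_mid <- NA
  for (i in seq_len(max_iter)) {
    a_mid <- sqrt(a_lo * a_hi)   # geometric bisection: Dice ~ log(amplitude)
    f_mid <- mean_dice(a_mid)
    if (abs(f_mid - target_dice) < tol) break
    if (f_mid > target_dice) a_lo <- a_mid else a_hi <- a_mid
  }
  list(amplitude_mm = a_mid, achieved_dice = f_mid)
}

## ------------------------------------------------------------ dose surrogate

#' Dose-surrogate parameters
#'
#' A stand-in for the treatment planning optimizer at the DVH level: dose
#' is a logistic function of the signed distance to the PTV, normalised so
#' PTV D95 equals the prescription, with optional smooth multiplicative
#' hot/cold-spot noise and optional per-organ dose caps emulating
#' constraint-driven optimisation.  No beam physics is modelled.
#'
#' @param prescription_gy prescription dose in Gy.
#' @param falloff_mm logistic falloff scale outside the PTV (mm).
#' @param bulge_mm conformity control: distance beyond the PTV surface at
#'   which the 95% isodose sits (0 = ideal conformity, CI near 1; larger
#'   values inflate the conformity index).
#' @param hotspot_frac amplitude of multiplicative hot/cold noise as a
#'   fraction of local dose (0 disables).
#' @param hotspot_corr_len_mm correlation length of the hot/cold field.
#' @param seed integer seed for the noise field.
#' @return an object of class `dose_model_params`.
#' @export
dose_model_params <- function(prescription_gy, falloff_mm = 3, bulge_mm = 2.5,
                              hotspot_frac = 0.02, hotspot_corr_len_mm = 25,
                              seed = 1) {
  stopifnot(prescription_gy > 0, falloff_mm > 0, bulge_mm >= 0,
            hotspot_frac >= 0)
  structure(list(prescription_gy = prescription_gy, falloff_mm = falloff_mm,
                 bulge_mm = bulge_mm, hotspot_frac = hotspot_frac,
                 hotspot_corr_len_mm = hotspot_corr_len_mm,
                 seed = as.integer(seed)),
            class = "dose_model_params")
}

#' Synthesize a conformal dose distribution for a PTV
#'
#' `D(x) = Rx * L((m - sdf(x)) / s)` with `L` the logistic function,
#' `s = falloff_mm` and `m = bulge_mm + s * log(19)` so the 95% isodose
#' sits `bulge_mm` outside the PTV surface; multiplied by the hot/cold
#' field, normalised so the PTV median dose equals the prescription, then capped
#' inside any organ listed in `oar_caps` (emulating an optimizer honouring
#' an organ constraint on the planned — i.e. the observer's own —
#' contours).  Deterministic given the parameter seed.
#' @param ptv non-empty PTV [structure_mask].
#' @param params a [dose_model_params].
#' @param oar_caps optional list of `list(mask =, cap_gy =)` entries; dose
#'   inside each mask is clamped to its cap.
#' @return a [dose_grid].
#' @export
synthesize_dose <- function(ptv, params, oar_caps = list()) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(params, "dose_model_params"))
  if (!any(ptv$occupancy)) stop("PTV is empty; cannot synthesize dose")
  grid <- ptv$grid
  s <- params$falloff_mm
  m <- params$bulge_mm + s * log(19)
  sdf <- signed_distance(ptv)
  d <- params$prescription_gy / (1 + exp((sdf - m) / s))
  if (params$hotspot_frac > 0) {
    f <- smooth_noise_field(grid, params$hotspot_corr_len_mm, params$seed)
    # heterogeneity is confined to the high-dose region: real optimizers
    # produce hot/cold spots inside the target while the penumbra shape is
    # governed by beam geometry and stays smooth, so the stochastic field
    # is weighted down steeply with the base dose level
    w <- (d / params$prescription_gy)^8
    d <- d * pmax(1 + params$hotspot_frac * f * w, 0)
  }
  # prescription normalisation: PTV median dose = Rx.  The median is robust
  # to the heterogeneity field, so the 95% isodose stays bulge_mm outside
  # the PTV surface instead of drifting with the coldest interior blob.
  dmed <- stats::median(d[ptv$occupancy])
  if (dmed > 0) d <- d * params$prescription_gy / dmed
  for (cap in oar_caps) {
    stopifnot(inherits(cap$mask, "structure_mask"), is.finite(cap$cap_gy))
    stop_if_incompatible(grid, cap$mask$grid)
    d[cap$mask$occupancy] <- pmin(d[cap$mask$occupancy], cap$cap_gy)
  }
  dose_grid(grid, d)
}
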