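# Voxel-grid data model and 3D morphology shared by every other module.
#
# Conventions (fixed across the package):
#   * patient-space millimetres, axis-aligned grids with identity direction
#     cosines; the z axis increases cranially;
#   * `origin` is the position of the CENTRE of voxel index (1,1,1);
#   * voxel-centre semantics everywhere: a voxel belongs to a region iff its
#     centre does.

#' Construct a voxel grid
#'
#' An axis-aligned anisotropic 3D sampling lattice in patient millimetre
#' coordinates.  `origin` locates the centre of the first voxel; `spacing`
#' may differ per axis (in-plane vs slice); the third axis is cranio-caudal.
#'
#' @param origin numeric length-3, mm position of the centre of voxel (1,1,1).
#' @param spacing numeric length-3, strictly positive voxel pitch in mm.
#' @param shape integer length-3, number of voxels per axis (each >= 1).
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(64, 64, 40))
#' voxel_volume_cc(g)
#' @export
voxel_grid <- function(origin, spacing, shape) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape_num <- suppressWarnings(as.numeric(shape))
  if (any(!is.finite(shape_num)) || any(shape_num != round(shape_num)))
    stop("grid shape must be whole numbers")
  shape <- as.integer(shape_num)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(shape) == 3)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be strictly positive")
  if (any(is.na(shape)) || any(shape < 1L))
    stop("grid shape must be >= 1 on every axis")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Volume of one voxel in cubic centimetres
#' @param grid a [voxel_grid].
#' @return scalar, `prod(spacing)/1000` cc.
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing) / 1000
}

#' Are two grids compatible?
#'
#' Cross-structure operations require exact equality of origin, spacing and
#' shape; resampling between grids is deliberately out of scope.
#' @param a,b [voxel_grid] objects.
#' @return logical scalar.
#' @export
grids_compatible <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  identical(a$origin, b$origin) && identical(a$spacing, b$spacing) &&
    identical(a$shape, b$shape)
}

stop_if_incompatible <- function(a, b) {
  if (!grids_compatible(a, b))
    stop("incompatible voxel grids: origin/spacing/shape must match exactly; resampling is not supported")
  invisible(TRUE)
}

#' Voxel-centre coordinates along one axis
#' @param grid a [voxel_grid].
#' @param axis 1 (x), 2 (y) or 3 (z, cranio-caudal).
#' @return numeric vector of mm coordinates of voxel centres.
#' @export
axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Construct a structure mask
#'
#' Named binary occupancy of a structure (target, organ at risk, or derived
#' volume) on a voxel grid.
#'
#' @param grid a [voxel_grid].
#' @param occupancy logical array with `dim == grid$shape`, or `NULL` for an
#'   all-false mask.
#' @param name label string (structure name, preserved verbatim).
#' @param role one of `"TARGET"`, `"OAR"`, `"DERIVED"`.
#' @param provenance optional list recording how a derived mask was produced.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(grid, occupancy = NULL, name = "structure",
                           role = c("OAR", "TARGET", "DERIVED"),
                           provenance = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  role <- match.arg(role)
  if (is.null(occupancy)) {
    occupancy <- array(FALSE, dim = grid$shape)
  } else {
    occupancy <- as.logical(occupancy)
    if (anyNA(occupancy)) stop("mask occupancy must not contain NA")
    dim(occupancy) <- NULL
    if (length(occupancy) != prod(grid$shape))
      stop("occupancy length does not match grid shape")
    dim(occupancy) <- grid$shape
  }
  structure(list(name = as.character(name), role = role, grid = grid,
                 occupancy = occupancy, provenance = provenance),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s' (%s): %d voxels set, %.3f cc on %d x %d x %d grid\n",
              x$name, x$role, sum(x$occupancy), volume_cc(x),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Structure volume in cc
#' @param mask a [structure_mask].
#' @return set-voxel count times voxel volume, in cc.
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume_cc(mask$grid)
}

#' Boolean set operations on compatible masks
#'
#' Union, intersection and difference of masks on the same grid.  The result
#' carries role `"DERIVED"`.
#' @param a,b [structure_mask] objects on compatible grids.
#' @param name name for the derived mask.
#' @return a [structure_mask].
#' @export
mask_union <- function(a, b, name = paste(a$name, "|", b$name)) {
  stop_if_incompatible(a$grid, b$grid)
  structure_mask(a$grid, a$occupancy | b$occupancy, name, "DERIVED")
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b, name = paste(a$name, "&", b$name)) {
  stop_if_incompatible(a$grid, b$grid)
  structure_mask(a$grid, a$occupancy & b$occupancy, name, "DERIVED")
}

#' @rdname mask_union
#' @export
mask_diff <- function(a, b, name = paste(a$name, "\\", b$name)) {
  stop_if_incompatible(a$grid, b$grid)
  structure_mask(a$grid, a$occupancy & !b$occupancy, name, "DERIVED")
}

#' Euclidean distance map to a mask
#'
#' Exact anisotropic Euclidean distance (mm) from every voxel centre to the
#' nearest set voxel centre, computed with a separable lower-envelope
#' distance transform.  An empty mask yields `Inf` everywhere.
#' @param mask a [structure_mask].
#' @return numeric array of distances (mm) with `dim == grid$shape`.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  g <- mask$grid
  d2 <- .edt_sq(as.logical(mask$occupancy), g$shape, g$spacing)
  d <- sqrt(d2)
  dim(d) <- g$shape
  d
}

#' Expand a mask by a Euclidean margin
#'
#' Isotropic-in-millimetres margin growth: the result contains every voxel
#' whose centre lies within `margin_mm` (inclusive) of a set voxel centre,
#' using the physical anisotropic spacing.  This is the operation used to
#' grow a planning CTV into a PTV.  Contraction (negative margins) is not
#' provided.
#' @param mask a [structure_mask].
#' @param margin_mm non-negative scalar margin in mm.
#' @param name name for the result (defaults to the input name).
#' @return a [structure_mask] containing the input.
#' @export
expand_mask <- function(mask, margin_mm, name = mask$name) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.finite(margin_mm) || margin_mm < 0)
    stop("margin_mm must be a non-negative finite scalar; contraction is not supported")
  if (margin_mm == 0) {
    out <- mask
    out$name <- name
    return(out)
  }
  d <- distance_map(mask)
  structure_mask(mask$grid, d <= margin_mm, name, mask$role,
                 provenance = list(op = "expand", margin_mm = margin_mm,
                                   input = mask$name))
}

#' Depth map inside a mask
#'
#' For voxels inside the mask, the Euclidean distance (mm) to the nearest
#' voxel centre outside it; a boundary voxel has positive depth (one spacing
#' step to the adjacent cleared voxel).  Outside the mask the depth is 0.
#' @param mask a [structure_mask].
#' @return numeric array (mm).
#' @export
depth_map <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  complement <- structure_mask(mask$grid, !mask$occupancy, "complement", "DERIVED")
  d <- distance_map(complement)
  d[!mask$occupancy] <- 0
  d
}

#' Trim a target to a maximum depth inside an organ
#'
#' Removes from `target` every voxel lying inside `organ` deeper than
#' `max_depth_mm` from the organ's exterior (e.g. "the CTV may extend only
#' 3 mm into the bladder").  Target voxels outside the organ are untouched;
#' the result never gains voxels.  `max_depth_mm = 0` removes the entire
#' organ interior from the target.
#' @param target,organ [structure_mask] objects on compatible grids.
#' @param max_depth_mm non-negative allowed penetration depth in mm.
#' @param name name for the result.
#' @return a [structure_mask], subset of `target`.
#' @export
trim_to_depth <- function(target, organ, max_depth_mm, name = target$name) {
  stopifnot(inherits(target, "structure_mask"), inherits(organ, "structure_mask"))
  stop_if_incompatible(target$grid, organ$grid)
  if (is.na(max_depth_mm) || max_depth_mm < 0)
    stop("max_depth_mm must be >= 0")
  dep <- depth_map(organ)
  keep <- target$occupancy & !(organ$occupancy & dep > max_depth_mm)
  structure_mask(target$grid, keep, name, target$role,
                 provenance = list(op = "trim_to_depth", organ = organ$name,
                                   max_depth_mm = max_depth_mm,
                                   input = target$name))
}

#' Crop a mask above an axial plane
#'
#' Clears every voxel whose slice-centre z coordinate exceeds `z_limit_mm`
#' (used e.g. to impose a superior evaluation limit on the bowel).  A limit
#' above or below the whole grid legally yields the identity or an empty
#' mask.
#' @param mask a [structure_mask].
#' @param z_limit_mm scalar mm; slices with centre z > limit are cleared.
#' @param name name for the result.
#' @return a [structure_mask], subset of `mask`.
#' @export
crop_above <- function(mask, z_limit_mm, name = mask$name) {
  stopifnot(inherits(mask, "structure_mask"), is.finite(z_limit_mm))
  z <- axis_coords(mask$grid, 3)
  occ <- mask$occupancy
  occ[, , z > z_limit_mm] <- FALSE
  structure_mask(mask$grid, occ, name, mask$role,
                 provenance = list(op = "crop_above", z_limit_mm = z_limit_mm,
                                   input = mask$name))
}

#' Maximum penetration depth of one structure into another
#'
#' The deepest point of `a` inside `organ`, measured as the maximum over
#' voxels of `a & organ` of the distance to the organ exterior.  Returns 0
#' when the structures are disjoint.
#' @param a,organ [structure_mask] objects on compatible grids.
#' @return scalar depth in mm.
#' @export
max_penetration_mm <- function(a, organ) {
  stop_if_incompatible(a$grid, organ$grid)
  inside <- a$occupancy & organ$occupancy
  if (!any(inside)) return(0)
  dep <- depth_map(organ)
  max(dep[inside])
}
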