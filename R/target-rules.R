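# Boolean target-generation rules: CTV -> planning CTV -> PTV, plus the
# cranial evaluation limit applied to the bowel.
#
# Rule order is fixed (and recorded): depth-limited bladder trim, then
# bowel subtraction, then margin expansion.  The PTV is NOT re-trimmed
# against organs at risk after expansion — the margin may therefore re-enter
# the bladder up to `bladder_trim_mm + ptv_margin_mm` deep and overlap the
# bowel up to `ptv_margin_mm`; this matters for bladder and bowel dose and
# is deliberate, mirroring a planning system that expands the final margin
# purely geometrically.

#' Planning-rule configuration
#'
#' @param bladder_trim_mm maximum CTV penetration depth retained inside the
#'   bladder (default 3 mm).
#' @param ptv_margin_mm isotropic CTVplan-to-PTV expansion margin (default
#'   3 mm).
#' @param bowel_cranial_limit_mm evaluation limit for the bowel, measured
#'   cranially from the superior extent of the CTV (default 15 mm).
#' @return an object of class `planning_rules`.
#' @export
planning_rules <- function(bladder_trim_mm = 3, ptv_margin_mm = 3,
                           bowel_cranial_limit_mm = 15) {
  if (any(c(bladder_trim_mm, ptv_margin_mm, bowel_cranial_limit_mm) < 0))
    stop("planning-rule parameters must be >= 0")
  structure(list(bladder_trim_mm = bladder_trim_mm,
                 ptv_margin_mm = ptv_margin_mm,
                 bowel_cranial_limit_mm = bowel_cranial_limit_mm,
                 rule_order = c("bladder_trim", "bowel_subtract", "expand")),
            class = "planning_rules")
}

#' Superior extent of a structure
#'
#' Centre z coordinate (mm) of the most cranial slice containing any set
#' voxel.
#' @param mask a non-empty [structure_mask].
#' @return scalar z in mm.
#' @export
superior_extent_mm <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  has <- apply(mask$occupancy, 3, any)
  if (!any(has)) stop("structure '", mask$name, "' is empty; no superior extent")
  axis_coords(mask$grid, 3)[max(which(has))]
}

#' Generate the planning CTV from the physician CTV
#'
#' `CTVplan = trim_to_depth(CTV, bladder, bladder_trim_mm) \ bowel`: the CTV
#' is allowed to extend only `bladder_trim_mm` into the bladder and is
#' subtracted out of the bowel.  The result is a subset of the CTV and
#' shares no voxel with the bowel.  An empty result (pathological anatomy)
#' is an error, never a silently empty target.
#' @param ctv,bladder,bowel [structure_mask] objects on compatible grids.
#' @param cfg a [planning_rules] configuration.
#' @return a [structure_mask] named `"CTVplan"`.
#' @export
make_ctvplan <- function(ctv, bladder, bowel, cfg = planning_rules()) {
  stopifnot(inherits(cfg, "planning_rules"))
  if (!any(ctv$occupancy)) stop("CTV is empty")
  stop_if_incompatible(ctv$grid, bladder$grid)
  stop_if_incompatible(ctv$grid, bowel$grid)
  trimmed <- trim_to_depth(ctv, bladder, cfg$bladder_trim_mm)
  plan <- trimmed$occupancy & !bowel$occupancy
  if (!any(plan))
    stop("CTVplan is empty after Boolean rules; anatomy is pathological for this rule set")
  structure_mask(ctv$grid, plan, "CTVplan", "TARGET",
                 provenance = list(op = "make_ctvplan", ctv = ctv$name,
                                   bladder = bladder$name, bowel = bowel$name,
                                   rules = unclass(cfg)))
}

#' Expand the planning CTV into the PTV
#'
#' Pure Euclidean expansion by `ptv_margin_mm`; no re-trimming against
#' organs at risk afterwards (see the module note above).
#' @param ctvplan non-empty [structure_mask].
#' @param cfg a [planning_rules] configuration.
#' @return a [structure_mask] named `"PTV"` containing `ctvplan`.
#' @export
make_ptv <- function(ctvplan, cfg = planning_rules()) {
  stopifnot(inherits(cfg, "planning_rules"))
  if (!any(ctvplan$occupancy)) stop("CTVplan is empty")
  out <- expand_mask(ctvplan, cfg$ptv_margin_mm, name = "PTV")
  out$role <- "TARGET"
  out$provenance <- list(op = "make_ptv", input = ctvplan$name,
                         rules = unclass(cfg))
  out
}

#' Apply the cranial evaluation limit to the bowel
#'
#' Crops the bowel above `superior_extent(CTV) + bowel_cranial_limit_mm`,
#' the superior limit instituted for both contour comparison and DVH
#' evaluation of the bowel.
#' @param bowel a [structure_mask].
#' @param ctv the (non-empty) CTV [structure_mask].
#' @param cfg a [planning_rules] configuration.
#' @return a [structure_mask] named `"Bowel_eval"`.
#' @export
limit_bowel <- function(bowel, ctv, cfg = planning_rules()) {
  stopifnot(inherits(cfg, "planning_rules"))
  if (!any(ctv$occupancy)) stop("CTV is empty; cranial bowel limit undefined")
  stop_if_incompatible(bowel$grid, ctv$grid)
  zlim <- superior_extent_mm(ctv) + cfg$bowel_cranial_limit_mm
  out <- crop_above(bowel, zlim, name = "Bowel_eval")
  out$provenance <- list(op = "limit_bowel", input = bowel$name,
                         ctv = ctv$name, z_limit_mm = zlim,
                         rules = unclass(cfg))
  out
}

#' Apply all planning rules to a bundle
#'
#' Derives `CTVplan`, `PTV` and `Bowel_eval` from a bundle's `CTV`,
#' `Bladder` and `Bowel` structures and stores them back under those
#' reserved names, with rule provenance attached to each derived mask.
#' @param bundle a [fraction_bundle] with CTV, bladder and bowel.
#' @param cfg a [planning_rules] configuration.
#' @param aliases optional structure-name alias map.
#' @return the bundle with the derived structures added.
#' @export
apply_planning_rules <- function(bundle, cfg = planning_rules(), aliases = NULL) {
  ctv <- get_structure(bundle, "CTV", aliases)
  bladder <- get_structure(bundle, "Bladder", aliases)
  bowel <- get_structure(bundle, "Bowel", aliases)
  ctvplan <- make_ctvplan(ctv, bladder, bowel, cfg)
  ptv <- make_ptv(ctvplan, cfg)
  beval <- limit_bowel(bowel, ctv, cfg)
  bundle <- set_structure(bundle, ctvplan)
  bundle <- set_structure(bundle, ptv)
  set_structure(bundle, beval)
}
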