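# DVH engine and scalar dose metrics.
#
# Scalar metrics are computed from the raw multiset of voxel doses inside a
# structure (never from the binned DVH).  Volume-indexed metrics use the
# voxel-centre accumulation convention: sorting doses hottest-first, voxel i
# occupies cumulative volume ((i - 0.5) * voxel_volume, (i + 0.5) *
# voxel_volume]; D at a requested volume interpolates linearly between the
# bracketing sorted doses.  No sub-voxel partial-volume model is applied.

#' Construct a dose grid
#'
#' Scalar absorbed dose in Gy on a voxel grid; all values must be finite
#' and non-negative.
#' @param grid a [voxel_grid].
#' @param values numeric array of doses (Gy) with `dim == grid$shape`.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.numeric(values)
  if (length(values) != prod(grid$shape))
    stop("dose values length does not match grid shape")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and >= 0 Gy")
  dim(values) <- grid$shape
  structure(list(grid = grid, values = values), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d voxels, dose range [%.3f, %.3f] Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

structure_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  stop_if_incompatible(dose$grid, mask$grid)
  if (!any(mask$occupancy))
    stop("structure '", mask$name, "' is empty; dose metrics are undefined")
  dose$values[mask$occupancy]
}

#' Cumulative dose-volume histogram
#'
#' Volume (cc) receiving at least each dose level, on uniform bin edges from
#' 0 to just above the structure maximum.  The first bin holds the total
#' structure volume; the curve is monotone non-increasing.
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on a compatible grid.
#' @param bin_width_gy uniform bin width in Gy (default 0.1).
#' @return an object of class `cumulative_dvh`: list with `structure`,
#'   `dose_gy` (bin edges), `volume_cc` (volume at-or-above each edge),
#'   `total_cc`.
#' @export
dvh <- function(dose, mask, bin_width_gy = 0.1) {
  stopifnot(bin_width_gy > 0)
  d <- structure_doses(dose, mask)
  vv <- voxel_volume_cc(mask$grid)
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  # volume at-or-above each edge
  counts <- vapply(edges, function(e) sum(d >= e), numeric(1))
  structure(list(structure = mask$name, dose_gy = edges,
                 volume_cc = counts * vv, total_cc = length(d) * vv,
                 bin_width_gy = bin_width_gy),
            class = "cumulative_dvh")
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("cumulative DVH for '%s': %.2f cc, %d bins of %.3g Gy\n",
              x$structure, x$total_cc, length(x$dose_gy), x$bin_width_gy))
  invisible(x)
}

#' Parse a dose-metric specification string
#'
#' The mini-grammar used in constraint tables: `"Dmean"`, `"Dmax"`,
#' `"D95%"` (minimum dose to the hottest 95% of the volume), `"D0.03cc"`
#' (minimum dose to the hottest 0.03 cc).
#' @param spec metric string.
#' @return list with `type` in `{"mean","max","pct","cc"}` and `arg`.
#' @export
parse_metric <- function(spec) {
  s <- trimws(spec)
  if (tolower(s) == "dmean") return(list(type = "mean", arg = NA_real_, spec = "Dmean"))
  if (tolower(s) == "dmax") return(list(type = "max", arg = NA_real_, spec = "Dmax"))
  m <- regmatches(s, regexec("^[Dd]([0-9.]+)%$", s))[[1]]
  if (length(m) == 2) {
    x <- as.numeric(m[2])
    if (!is.finite(x) || x <= 0 || x > 100)
      stop("volume percentage must lie in (0, 100]: ", spec)
    return(list(type = "pct", arg = x, spec = paste0("D", m[2], "%")))
  }
  m <- regmatches(s, regexec("^[Dd]([0-9.]+) ?cc$", s))[[1]]
  if (length(m) == 2) {
    v <- as.numeric(m[2])
    if (!is.finite(v) || v <= 0) stop("volume in cc must be positive: ", spec)
    return(list(type = "cc", arg = v, spec = paste0("D", m[2], "cc")))
  }
  stop("unrecognised dose metric spec: '", spec,
       "' (expected Dmean, Dmax, D<x>%, or D<v>cc)")
}

# interpolated dose at cumulative hottest volume v_cc
dose_at_volume <- function(sorted_desc, vv_cc, v_cc) {
  n <- length(sorted_desc)
  if (v_cc > n * vv_cc + 1e-12)
    stop(sprintf("requested volume %.4g cc exceeds structure volume %.4g cc",
                 v_cc, n * vv_cc))
  k <- v_cc / vv_cc + 0.5           # voxel-centre accumulation position
  if (k <= 1) return(sorted_desc[1])
  if (k >= n) return(sorted_desc[n])
  lo <- floor(k)
  w <- k - lo
  sorted_desc[lo] * (1 - w) + sorted_desc[lo + 1] * w
}

#' Scalar dose metric for a structure
#'
#' * `Dmean`: volume-weighted mean voxel dose (equal voxel volumes: plain
#'   mean).
#' * `Dmax`: maximum voxel dose.
#' * `D<x>%`: minimum dose received by the hottest x% of the structure
#'   volume, x in (0, 100].
#' * `D<v>cc`: minimum dose received by the hottest v cc; errors if v
#'   exceeds the structure volume.
#' Volume-indexed metrics interpolate linearly on the sorted voxel-dose
#' accumulation (see the conventions note at the top of the DVH docs).
#' @param dose a [dose_grid].
#' @param mask a non-empty [structure_mask] on a compatible grid.
#' @param spec metric string (see [parse_metric()]) or a parsed metric.
#' @return scalar dose in Gy.
#' @export
dose_metric <- function(dose, mask, spec) {
  m <- if (is.list(spec)) spec else parse_metric(spec)
  d <- structure_doses(dose, mask)
  switch(m$type,
         mean = mean(d),
         max = max(d),
         pct = {
           vv <- voxel_volume_cc(mask$grid)
           dose_at_volume(sort(d, decreasing = TRUE), vv,
                          m$arg / 100 * length(d) * vv)
         },
         cc = {
           vv <- voxel_volume_cc(mask$grid)
           dose_at_volume(sort(d, decreasing = TRUE), vv, m$arg)
         },
         stop("unknown metric type"))
}

#' RTOG conformity index
#'
#' `CI = V_RI / V_PTV`, where `V_RI` is the total volume of all voxels —
#' anywhere in the dose grid, not only inside the PTV — receiving at least
#' 95% of the prescription dose (inclusive threshold).  Values near 1
#' indicate a conformal plan; spill of the 95% isodose outside the target
#' inflates the index.
#' @param dose a [dose_grid].
#' @param ptv non-empty PTV [structure_mask] on a compatible grid.
#' @param prescription_gy prescription dose in Gy (> 0).
#' @return dimensionless scalar.
#' @export
conformity_index <- function(dose, ptv, prescription_gy) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ptv, "structure_mask"))
  stop_if_incompatible(dose$grid, ptv$grid)
  if (!is.finite(prescription_gy) || prescription_gy <= 0)
    stop("prescription must be positive")
  nptv <- sum(ptv$occupancy)
  if (nptv == 0) stop("PTV is empty; conformity index undefined")
  vri <- sum(dose$values >= 0.95 * prescription_gy)
  vri / nptv
}
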