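# Contour agreement metrics: Dice similarity index, pairwise observer
# comparison tables, and the one-way ANOVA used to compare comparison
# groups.

#' Dice similarity index between two masks
#'
#' `DSI = 2 |A & B| / (|A| + |B|)` on voxel counts.  Symmetric, 1 iff the
#' masks are identical, 0 iff disjoint.  Two empty masks are an explicit
#' error (a silent 1 or 0 would hide a missing contour).
#' @param ref,test [structure_mask] objects on compatible grids.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(ref, test) {
  stopifnot(inherits(ref, "structure_mask"), inherits(test, "structure_mask"))
  stop_if_incompatible(ref$grid, test$grid)
  na <- sum(ref$occupancy); nb <- sum(test$occupancy)
  if (na == 0 && nb == 0)
    stop("Dice index undefined: both masks are empty (missing contours?)")
  2 * sum(ref$occupancy & test$occupancy) / (na + nb)
}

#' Pairwise Dice comparison table
#'
#' For a set of fraction bundles contoured by several observers, compares
#' each observer against a reference observer, per structure, and reports
#' the mean and sample (n-1) standard deviation of the Dice index over all
#' fractions.  The physician-vs-physician pair can be flagged as the
#' benchmark row against which the others are judged.
#'
#' @param bundles list of [fraction_bundle] objects; every observer must
#'   have contoured every requested structure for every (patient, fraction).
#' @param reference observer id used as the reference contourer.
#' @param structures character vector of structure names to compare.
#' @param benchmark optional observer id whose pair with the reference is
#'   the benchmark (e.g. the second physician).
#' @param aliases optional structure-name alias map (see [get_structure()]).
#' @return a data frame of class `pairwise_dsi_table` with columns `pair`,
#'   `structure`, `mean`, `sd`, `n`, `benchmark`, plus attribute `values`
#'   holding the per-fraction Dice values.
#' @export
pairwise_dsi <- function(bundles, reference, structures,
                         benchmark = NULL, aliases = NULL) {
  obs <- vapply(bundles, function(b) b$observer_id, character(1))
  frk <- vapply(bundles, function(b) paste(b$patient_id, b$fraction_id, sep = "/"),
                character(1))
  if (!reference %in% obs) stop("reference observer '", reference, "' absent")
  fractions <- unique(frk)
  others <- setdiff(unique(obs), reference)
  # completeness check: every (observer, fraction, structure) must exist
  gaps <- character(0)
  idx <- function(o, f) which(obs == o & frk == f)
  for (o in c(reference, others)) for (f in fractions) {
    i <- idx(o, f)
    if (length(i) != 1) { gaps <- c(gaps, paste(o, f, sep = " @ ")); next }
    for (s in structures) {
      ok <- tryCatch({ get_structure(bundles[[i]], s, aliases); TRUE },
                     error = function(e) FALSE)
      if (!ok) gaps <- c(gaps, paste(o, f, s, sep = " @ "))
    }
  }
  if (length(gaps) > 0)
    stop("missing (observer, fraction, structure) entries:\n  ",
         paste(gaps, collapse = "\n  "))
  rows <- list()
  values <- list()
  for (o in others) {
    for (s in structures) {
      v <- vapply(fractions, function(f) {
        dice(get_structure(bundles[[idx(reference, f)]], s, aliases),
             get_structure(bundles[[idx(o, f)]], s, aliases))
      }, numeric(1))
      pair <- paste(reference, "v", o)
      values[[paste(pair, s)]] <- unname(v)
      rows[[length(rows) + 1]] <- data.frame(
        pair = pair, structure = s, mean = mean(v),
        sd = if (length(v) > 1) sd(v) else 0, n = length(v),
        benchmark = isTRUE(!is.null(benchmark) && !is.na(benchmark) &&
                             o == benchmark),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "values") <- values
  class(out) <- c("pairwise_dsi_table", class(out))
  out
}

#' One-way fixed-effects ANOVA
#'
#' Classical equal-variance one-way ANOVA across groups of scalars, as used
#' to compare Dice or conformity values between observer pairs; differences
#' are flagged significant at `alpha`.
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2 finite
#'   values).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `df_between`, `df_within`, `p_value`,
#'   `significant`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least two values")
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals))) stop("group values must be finite")
  g <- factor(rep(seq_along(groups), sizes))
  # degenerate: no variance anywhere -> F is 0/0
  if (all(vals == vals[1]))
    stop("degenerate ANOVA: zero between-group and zero within-group variance")
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  Fv <- unname(ft$statistic)
  p <- unname(ft$p.value)
  # identical group means with within-group variance: F = 0, p = 1
  if (is.na(Fv)) { Fv <- 0; p <- 1 }
  list(F = Fv,
       df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]),
       p_value = p,
       significant = p < alpha)
}
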