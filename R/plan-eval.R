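# Tiered constraint classification, gold-standard overlay re-evaluation,
# and workflow outcome aggregation.
#
# Tier semantics (boundary equality always belongs to the better tier, i.e.
# the printed "<=" limits are inclusive):
#   value <= ideal               -> MET
#   ideal < value <= acceptable  -> ACCEPTABLE_VARIATION
#   value > acceptable           -> FAIL
# A plan's tier is its worst constraint tier.  "Pass" means MET or
# ACCEPTABLE_VARIATION.

TIER_LEVELS <- c("MET", "ACCEPTABLE_VARIATION", "FAIL")
DISPOSITIONS <- c("DELIVERED_OK", "HALTED_FOR_REVIEW", "DELIVERED_SUBOPTIMAL")

#' Prescription specification
#'
#' Dose per fraction determines the constraint tier: conventional
#' fractionation (1.8-2 Gy/fraction) or short course (5 Gy/fraction).  Any
#' other dose per fraction has no constraint mapping and errors.
#' @param dose_per_fraction Gy per fraction.
#' @param n_fractions number of fractions (total = dose_per_fraction * n).
#' @return an object of class `prescription_spec` with fields
#'   `dose_per_fraction`, `n_fractions`, `total_gy`, `tier`.
#' @export
prescription_spec <- function(dose_per_fraction, n_fractions) {
  stopifnot(is.finite(dose_per_fraction), is.finite(n_fractions),
            n_fractions >= 1)
  tier <- if (dose_per_fraction >= 1.8 && dose_per_fraction <= 2) "CONVENTIONAL"
  else if (dose_per_fraction == 5) "SHORT"
  else stop("no constraint tier is defined for ", dose_per_fraction,
            " Gy/fraction (conventional: 1.8-2, short: 5)")
  structure(list(dose_per_fraction = dose_per_fraction,
                 n_fractions = as.integer(n_fractions),
                 total_gy = dose_per_fraction * n_fractions,
                 tier = tier),
            class = "prescription_spec")
}

#' @export
print.prescription_spec <- function(x, ...) {
  cat(sprintf("prescription: %.4g Gy/fx x %d = %.4g Gy (%s)\n",
              x$dose_per_fraction, x$n_fractions, x$total_gy, x$tier))
  invisible(x)
}

#' One dosimetric constraint with ideal and acceptable-variation limits
#'
#' Upper-bound constraints only (the protocol constrains organ-at-risk
#' dose from above); `ideal_gy <= acceptable_gy` is enforced.
#' @param structure structure name the constraint applies to.
#' @param metric dose-metric spec string (see [parse_metric()]).
#' @param ideal_gy ideal (protocol-met) limit in Gy.
#' @param acceptable_gy acceptable-variation limit in Gy.
#' @return an object of class `constraint_spec`.
#' @export
constraint_spec <- function(structure, metric, ideal_gy, acceptable_gy) {
  parse_metric(metric)  # validates
  if (!(ideal_gy <= acceptable_gy))
    stop("ideal limit must not exceed the acceptable-variation limit")
  structure(list(structure = structure, metric = metric,
                 ideal_gy = ideal_gy, acceptable_gy = acceptable_gy,
                 direction = "upper"),
            class = "constraint_spec")
}

#' Default organ-at-risk constraint set by prescription tier
#'
#' Conventional fractionation (1.8-2 Gy/fx): bladder Dmean <= 40 Gy
#' (acceptable <= 44 Gy), bowel D0.03cc <= 50 Gy (acceptable <= 55 Gy).
#' Short course (5 Gy/fx): bladder Dmean <= 22 Gy (acceptable <= 24 Gy),
#' bowel D0.03cc <= 27.5 Gy (acceptable <= 30 Gy).  The bowel constraint is
#' evaluated on the cranially limited bowel (`Bowel_eval`).
#' @param rx a [prescription_spec].
#' @return list of [constraint_spec] objects.
#' @export
default_constraints <- function(rx) {
  stopifnot(inherits(rx, "prescription_spec"))
  if (rx$tier == "CONVENTIONAL") {
    list(constraint_spec("Bladder", "Dmean", 40, 44),
         constraint_spec("Bowel_eval", "D0.03cc", 50, 55))
  } else {
    list(constraint_spec("Bladder", "Dmean", 22, 24),
         constraint_spec("Bowel_eval", "D0.03cc", 27.5, 30))
  }
}

tier_of <- function(value, ideal, acceptable) {
  if (value <= ideal) "MET"
  else if (value <= acceptable) "ACCEPTABLE_VARIATION"
  else "FAIL"
}

worst_tier <- function(tiers) TIER_LEVELS[max(match(tiers, TIER_LEVELS))]

#' Classify a dose distribution against a constraint set
#'
#' Evaluates each constraint's metric on the named structure and assigns a
#' tier; the plan tier is the worst constraint tier.  A missing or empty
#' structure is an error naming it.
#' @param dose a [dose_grid].
#' @param structures named list of [structure_mask] objects.
#' @param constraints list of [constraint_spec] objects.
#' @param aliases optional structure-name alias map.
#' @return an object of class `tier_result`: data frame (`structure`,
#'   `metric`, `value_gy`, `ideal_gy`, `acceptable_gy`, `tier`) with
#'   attribute `plan_tier`.
#' @export
classify <- function(dose, structures, constraints, aliases = NULL) {
  stopifnot(inherits(dose, "dose_grid"), length(constraints) > 0)
  rows <- lapply(constraints, function(cs) {
    stopifnot(inherits(cs, "constraint_spec"))
    mask <- find_structure(structures, cs$structure, aliases)
    val <- dose_metric(dose, mask, cs$metric)
    data.frame(structure = cs$structure, metric = cs$metric,
               value_gy = val, ideal_gy = cs$ideal_gy,
               acceptable_gy = cs$acceptable_gy,
               tier = tier_of(val, cs$ideal_gy, cs$acceptable_gy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "plan_tier") <- worst_tier(out$tier)
  class(out) <- c("tier_result", class(out))
  out
}

#' Plan tier of a classification
#' @param result a `tier_result` from [classify()].
#' @return `"MET"`, `"ACCEPTABLE_VARIATION"` or `"FAIL"`.
#' @export
plan_tier <- function(result) {
  stopifnot(inherits(result, "tier_result"))
  attr(result, "plan_tier")
}

#' Re-evaluate an observer's dose on the gold-standard structures
#'
#' The specialist's contours ("gold standard") are overlaid onto the
#' observer's plan: the observer's DOSE is classified against the GOLD
#' structures, with no resampling (grids must match exactly).  Returned
#' alongside the clinical classification, this reveals plans that pass on
#' the observer's own contours but miss the true anatomy.
#' @param observer_bundle a [fraction_bundle] with dose.
#' @param gold_structures named list of gold-standard [structure_mask]s.
#' @param constraints list of [constraint_spec] objects.
#' @param aliases optional structure-name alias map.
#' @return a `tier_result`.
#' @export
gold_overlay_eval <- function(observer_bundle, gold_structures, constraints,
                              aliases = NULL) {
  stopifnot(inherits(observer_bundle, "fraction_bundle"))
  if (is.null(observer_bundle$dose))
    stop("observer bundle carries no dose to re-evaluate")
  for (s in gold_structures)
    stop_if_incompatible(observer_bundle$dose$grid, s$grid)
  classify(observer_bundle$dose, gold_structures, constraints, aliases)
}

#' Per-fraction workflow outcome
#'
#' Combines the clinical classification (observer's own structures) and the
#' gold-standard classification (specialist structures under the observer's
#' dose) into one of three mutually exclusive workflow dispositions:
#' * `HALTED_FOR_REVIEW` — the clinical evaluation failed, so the workflow
#'   stops the delivery for physician review (a safe outcome);
#' * `DELIVERED_SUBOPTIMAL` — clinically passing but failing on the gold
#'   structures: a silent failure that only offline review would catch;
#' * `DELIVERED_OK` — otherwise.
#' @param patient_id,fraction_id,observer_id identifiers.
#' @param clinical,gold `tier_result` objects (or tier strings).
#' @param observer_class e.g. `"physician"`, `"therapist"`, `"student"`.
#' @return an object of class `fraction_outcome`.
#' @export
fraction_outcome <- function(patient_id, fraction_id, observer_id,
                             clinical, gold, observer_class = "observer") {
  ct <- if (inherits(clinical, "tier_result")) plan_tier(clinical) else
    match.arg(clinical, TIER_LEVELS)
  gt <- if (inherits(gold, "tier_result")) plan_tier(gold) else
    match.arg(gold, TIER_LEVELS)
  disposition <- if (ct == "FAIL") "HALTED_FOR_REVIEW"
  else if (gt == "FAIL") "DELIVERED_SUBOPTIMAL"
  else "DELIVERED_OK"
  structure(list(patient_id = patient_id, fraction_id = fraction_id,
                 observer_id = observer_id, observer_class = observer_class,
                 clinical_tier = ct, gold_tier = gt,
                 disposition = disposition,
                 clinical_detail = if (inherits(clinical, "tier_result")) clinical,
                 gold_detail = if (inherits(gold, "tier_result")) gold),
            class = "fraction_outcome")
}

outcomes_frame <- function(outcomes) {
  stopifnot(length(outcomes) > 0)
  do.call(rbind, lapply(outcomes, function(o) {
    stopifnot(inherits(o, "fraction_outcome"))
    data.frame(patient_id = o$patient_id, fraction_id = o$fraction_id,
               observer_id = o$observer_id, observer_class = o$observer_class,
               clinical_tier = o$clinical_tier, gold_tier = o$gold_tier,
               disposition = o$disposition, stringsAsFactors = FALSE)
  }))
}

# half-even rounding to one decimal, with raw counts kept alongside so
# rounding can never hide a discrepancy
rate_pct <- function(num, den) round(100 * num / den, 1)

summarise_group <- function(df) {
  n <- nrow(df)
  cpass <- sum(df$clinical_tier != "FAIL")
  gpass <- sum(df$gold_tier != "FAIL")
  safe <- sum(df$disposition %in% c("DELIVERED_OK", "HALTED_FOR_REVIEW"))
  list(n = n,
       clinical = list(met = sum(df$clinical_tier == "MET"),
                       acceptable = sum(df$clinical_tier == "ACCEPTABLE_VARIATION"),
                       fail = sum(df$clinical_tier == "FAIL"),
                       pass = cpass, pass_rate_pct = rate_pct(cpass, n)),
       gold = list(met = sum(df$gold_tier == "MET"),
                   acceptable = sum(df$gold_tier == "ACCEPTABLE_VARIATION"),
                   fail = sum(df$gold_tier == "FAIL"),
                   pass = gpass, pass_rate_pct = rate_pct(gpass, n)),
       dispositions = as.list(table(factor(df$disposition, DISPOSITIONS))),
       safety = list(safe = safe, safety_rate_pct = rate_pct(safe, n),
                     treated_after_fail = n - safe,
                     treated_after_fail_pct = rate_pct(n - safe, n)))
}

#' Aggregate fraction outcomes into a workflow summary
#'
#' Reports, overall and per observer class: the clinical pass rate
#' (MET + ACCEPTABLE_VARIATION over N), the gold-standard pass rate, the
#' disposition counts, and the workflow safety rate — the fraction of plans
#' either correctly delivered or halted for review before delivery
#' (`DELIVERED_OK + HALTED_FOR_REVIEW` over N).  Its complement is the
#' treated-after-failing rate.  Percentages are rounded half-even to one
#' decimal; raw numerators and denominators are always reported alongside.
#' Also cross-tabulates clinical x gold tiers (the outcome-matrix counts).
#' @param outcomes non-empty list of [fraction_outcome] objects.
#' @return an object of class `workflow_summary`.
#' @export
aggregate_outcomes <- function(outcomes) {
  df <- outcomes_frame(outcomes)
  per_class <- lapply(split(df, df$observer_class), summarise_group)
  xt <- table(clinical = factor(df$clinical_tier, TIER_LEVELS),
              gold = factor(df$gold_tier, TIER_LEVELS))
  structure(list(overall = summarise_group(df), per_class = per_class,
                 crosstab = xt, outcomes = df),
            class = "workflow_summary")
}

#' @export
print.workflow_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("workflow summary over %d fraction evaluations\n", o$n))
  cat(sprintf("  clinical pass: %d/%d (%.1f%%)  [MET %d, ACC %d, FAIL %d]\n",
              o$clinical$pass, o$n, o$clinical$pass_rate_pct,
              o$clinical$met, o$clinical$acceptable, o$clinical$fail))
  cat(sprintf("  gold pass:     %d/%d (%.1f%%)  [MET %d, ACC %d, FAIL %d]\n",
              o$gold$pass, o$n, o$gold$pass_rate_pct,
              o$gold$met, o$gold$acceptable, o$gold$fail))
  cat(sprintf("  safety rate:   %d/%d (%.1f%%); treated after failing: %d (%.1f%%)\n",
              o$safety$safe, o$n, o$safety$safety_rate_pct,
              o$safety$treated_after_fail, o$safety$treated_after_fail_pct))
  for (cl in names(x$per_class)) {
    g <- x$per_class[[cl]]
    cat(sprintf("  [%s] n=%d clinical %.1f%% gold %.1f%% safety %.1f%%\n",
                cl, g$n, g$clinical$pass_rate_pct, g$gold$pass_rate_pct,
                g$safety$safety_rate_pct))
  }
  invisible(x)
}

#' Per-fraction outcome matrix
#'
#' Serializable three-state grid: one row per (patient, fraction), one
#' column pair per observer (clinical and gold evaluation basis), each cell
#' `MET`, `ACCEPTABLE_VARIATION` or `FAIL` — the table behind the outcome
#' heat map.
#' @param outcomes non-empty list of [fraction_outcome] objects.
#' @return data frame of class `outcome_matrix`; rows are fractions, paired
#'   columns `<observer>.clinical` / `<observer>.gold`.
#' @export
outcome_matrix <- function(outcomes) {
  df <- outcomes_frame(outcomes)
  frk <- unique(df[, c("patient_id", "fraction_id")])
  obs <- unique(df$observer_id)
  out <- frk
  for (o in obs) {
    for (basis in c("clinical", "gold")) {
      col <- vapply(seq_len(nrow(frk)), function(i) {
        hit <- df$observer_id == o & df$patient_id == frk$patient_id[i] &
          df$fraction_id == frk$fraction_id[i]
        if (!any(hit)) NA_character_ else
          df[[paste0(basis, "_tier")]][which(hit)[1]]
      }, character(1))
      out[[paste(o, basis, sep = ".")]] <- col
    }
  }
  class(out) <- c("outcome_matrix", class(out))
  out
}

#' Render an outcome matrix as a heat map
#'
#' Green = constraints met, yellow = acceptable variation, red = failed;
#' rows are fractions, columns observer x evaluation basis.
#' @param m an [outcome_matrix()] result.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the integer matrix drawn.
#' @export
plot_outcome_matrix <- function(m, file = NULL) {
  stopifnot(inherits(m, "outcome_matrix"))
  cols <- setdiff(names(m), c("patient_id", "fraction_id"))
  z <- vapply(cols, function(cn) match(m[[cn]], TIER_LEVELS), numeric(nrow(m)))
  z <- matrix(z, nrow = nrow(m), dimnames = list(
    paste(m$patient_id, m$fraction_id, sep = "/"), cols))
  if (!is.null(file)) {
    png(file, width = 160 + 28 * ncol(z), height = 120 + 16 * nrow(z))
    on.exit(dev.off())
  }
  op <- par(mar = c(6, 6, 2, 1))
  on.exit(par(op), add = TRUE)
  image(x = seq_len(ncol(z)), y = seq_len(nrow(z)), z = t(z),
        zlim = c(1, 3), col = c("#2e7d32", "#f9a825", "#c62828"),
        axes = FALSE, xlab = "", ylab = "")
  axis(1, at = seq_len(ncol(z)), labels = colnames(z), las = 2, cex.axis = 0.7)
  axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 2, cex.axis = 0.6)
  box()
  invisible(z)
}
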