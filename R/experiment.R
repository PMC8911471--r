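# End-to-end experiments: phantom cohort -> target rules -> dose surrogate
# -> constraint evaluation -> workflow summary.
#
# The two-stage design (simulate, then evaluate) means real DICOM-derived
# bundles can replace phantom bundles without code changes: `run_evaluate`
# only sees the bundle directory and its manifest.

CONFIG_KEYS <- list(
  top = c("grid", "master_seed", "n_fractions", "deformation_amplitude_mm",
          "deformation_corr_len_mm", "rules", "dose_model", "patients",
          "observers", "gold_observer"),
  grid = c("origin", "spacing", "shape"),
  rules = c("bladder_trim_mm", "ptv_margin_mm", "bowel_cranial_limit_mm"),
  dose_model = c("falloff_mm", "bulge_mm", "hotspot_frac",
                 "hotspot_corr_len_mm", "oar_cap"),
  patient = c("id", "dose_per_fraction", "n_fractions_rx", "ctv_scale",
              "penetration_mm", "bowel_z_range", "bowel_radius"),
  observer = c("id", "class", "noise_amplitude_mm", "corr_len_mm", "bias_mm"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown config key(s) in ", where, ": ", paste(extra, collapse = ", "))
}

#' Default experiment configuration
#'
#' A 10-patient cohort (six conventionally fractionated at 1.8-2 Gy per
#' fraction, four short-course at 5 Gy per fraction), 2 simulated fractions
#' per patient, and six observers: two physicians (the first is the
#' specialist whose contours are the gold standard and the simulation
#' truth), three therapists and one student, with noise amplitudes chosen
#' to emulate the high-agreement regime of trained observers (expected
#' Dice roughly 0.96-0.99).  Patient 5 carries a deliberately large target
#' abutting the bowel — the challenging-anatomy case.
#' @param master_seed integer master seed; every stream in the experiment
#'   is derived from it.
#' @return a config list accepted by [run_simulate()].
#' @export
default_experiment_config <- function(master_seed = 20220223) {
  pat <- function(id, dpf, nfx, ctv_scale = 1, penetration_mm = 10)
    list(id = id, dose_per_fraction = dpf, n_fractions_rx = nfx,
         ctv_scale = ctv_scale, penetration_mm = penetration_mm)
  obs <- function(id, class, amp, bias = 0)
    list(id = id, class = class, noise_amplitude_mm = amp,
         corr_len_mm = 10, bias_mm = bias)
  list(
    grid = list(origin = c(0, 0, 0), spacing = c(1.5, 1.5, 3),
                shape = c(80L, 80L, 50L)),
    master_seed = as.integer(master_seed),
    n_fractions = 2L,
    deformation_amplitude_mm = 4,
    deformation_corr_len_mm = 30,
    rules = list(bladder_trim_mm = 3, ptv_margin_mm = 3,
                 bowel_cranial_limit_mm = 15),
    dose_model = list(falloff_mm = 3, bulge_mm = 2.5, hotspot_frac = 0.02,
                      hotspot_corr_len_mm = 25, oar_cap = TRUE),
    patients = list(
      pat("P01", 2.0, 25L), pat("P02", 5.0, 5L), pat("P03", 1.8, 28L),
      pat("P04", 5.0, 5L), pat("P05", 2.0, 28L, ctv_scale = 1.25),
      pat("P06", 1.8, 25L), pat("P07", 1.8, 25L), pat("P08", 5.0, 3L),
      pat("P09", 5.0, 5L), pat("P10", 1.8, 25L)),
    observers = list(
      obs("D1", "physician", 0), obs("D2", "physician", 0.8),
      obs("T1", "therapist", 1.1), obs("T2", "therapist", 1.1),
      obs("T3", "therapist", 1.4), obs("S1", "student", 1.7)),
    gold_observer = "D1")
}

validate_config <- function(cfg) {
  check_keys(cfg, CONFIG_KEYS$top, "config")
  for (req in c("grid", "master_seed", "patients", "observers"))
    if (is.null(cfg[[req]])) stop("config lacks required key '", req, "'")
  check_keys(cfg$grid, CONFIG_KEYS$grid, "grid")
  check_keys(cfg$rules %||% list(), CONFIG_KEYS$rules, "rules")
  check_keys(cfg$dose_model %||% list(), CONFIG_KEYS$dose_model, "dose_model")
  for (p in cfg$patients) {
    check_keys(p, CONFIG_KEYS$patient, paste0("patient ", p$id %||% "?"))
    prescription_spec(p$dose_per_fraction, p$n_fractions_rx)  # validates tier
  }
  for (o in cfg$observers)
    check_keys(o, CONFIG_KEYS$observer, paste0("observer ", o$id %||% "?"))
  gold <- cfg$gold_observer %||% "D1"
  if (!gold %in% vapply(cfg$observers, `[[`, character(1), "id"))
    stop("gold observer '", gold, "' is not among the observers")
  invisible(cfg)
}

#' Read an experiment configuration from a YAML or JSON file
#' @param path config file path.
#' @return validated config list.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

patient_anatomy <- function(cfg, p) {
  base <- anatomy_params(seed = derive_seed(cfg$master_seed, "anatomy", p$id),
                         jitter_frac = 0.06)
  sc <- p$ctv_scale %||% 1
  base$ctv$semiaxes <- base$ctv$semiaxes * sc
  base$ctv$penetration_mm <- p$penetration_mm %||% 10
  if (!is.null(p$bowel_z_range)) base$bowel$z_range <- p$bowel_z_range
  if (!is.null(p$bowel_radius)) base$bowel$radius <- p$bowel_radius
  base
}

observer_from_cfg <- function(o) {
  observer_profile(o$id, o$class %||% "therapist",
                   noise_amplitude_mm = o$noise_amplitude_mm %||% 1,
                   corr_len_mm = o$corr_len_mm %||% 10,
                   bias_mm = o$bias_mm %||% 0)
}

# build one observer's adapted plan for one fraction: contours -> Boolean
# rules -> synthesized dose (with the optimizer-like cap applied to the
# observer's OWN evaluated bowel)
adapt_plan <- function(truth, profile, rx, cfg, rules_cfg, seed_obs, seed_dose) {
  b <- generate_observer_contours(truth, profile, seed_obs)
  b <- apply_planning_rules(b, rules_cfg)
  b$prescription <- rx
  dm <- cfg$dose_model %||% list()
  params <- dose_model_params(rx$total_gy,
                              falloff_mm = dm$falloff_mm %||% 3,
                              bulge_mm = dm$bulge_mm %||% 2.5,
                              hotspot_frac = dm$hotspot_frac %||% 0.02,
                              hotspot_corr_len_mm = dm$hotspot_corr_len_mm %||% 25,
                              seed = seed_dose)
  caps <- list()
  if (isTRUE(dm$oar_cap %||% TRUE)) {
    bowel_ideal <- if (rx$tier == "CONVENTIONAL") 50 else 27.5
    caps <- list(list(mask = get_structure(b, "Bowel_eval"),
                      cap_gy = bowel_ideal * 0.995))
  }
  b$dose <- synthesize_dose(get_structure(b, "PTV"), params, caps)
  b
}

#' Simulate a phantom cohort to disk
#'
#' Generates, for every (patient, fraction, observer), the observer's
#' adapted plan bundle — perturbed contours, derived CTVplan/PTV/limited
#' bowel, and the surrogate dose — and writes each as a bundle archive plus
#' a `manifest.json` listing every file with its md5 digest and the full
#' serialized configuration (same config + seed => byte-identical digests).
#' The gold observer's bundle doubles as the gold-standard structure set.
#' @param cfg config list (see [default_experiment_config()]).
#' @param out_dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @param quiet suppress progress messages.
#' @return path to the manifest, invisibly.
#' @export
run_simulate <- function(cfg, out_dir, force = FALSE, quiet = FALSE) {
  validate_config(cfg)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- voxel_grid(cfg$grid$origin, cfg$grid$spacing, cfg$grid$shape)
  rules_cfg <- do.call(planning_rules, cfg$rules %||% list())
  profiles <- lapply(cfg$observers, observer_from_cfg)
  names(profiles) <- vapply(profiles, `[[`, character(1), "id")
  files <- list()
  for (p in cfg$patients) {
    rx <- prescription_spec(p$dose_per_fraction, p$n_fractions_rx)
    planning <- generate_planning_case(patient_anatomy(cfg, p), grid,
                                       patient_id = p$id)
    for (f in seq_len(cfg$n_fractions %||% 2L)) {
      fid <- sprintf("F%d", f)
      truth <- generate_fraction(planning, cfg$deformation_amplitude_mm %||% 4,
                                 derive_seed(cfg$master_seed, "fraction", p$id, f),
                                 fraction_id = fid,
                                 corr_len_mm = cfg$deformation_corr_len_mm %||% 30)
      for (prof in profiles) {
        b <- adapt_plan(truth, prof, rx, cfg, rules_cfg,
                        seed_obs = derive_seed(cfg$master_seed, "obs", p$id, f, prof$id),
                        seed_dose = derive_seed(cfg$master_seed, "dose", p$id, f, prof$id))
        fn <- sprintf("%s_%s_%s.aqb", p$id, fid, prof$id)
        write_bundle(b, file.path(out_dir, fn))
        files[[length(files) + 1]] <- list(
          path = fn, patient = p$id, fraction = fid, observer = prof$id,
          observer_class = prof$class,
          md5 = unname(tools::md5sum(file.path(out_dir, fn))))
      }
      if (!quiet) message("simulated ", p$id, "/", fid)
    }
  }
  manifest <- list(format = "adaptqa-manifest", version = 1L,
                   gold_observer = cfg$gold_observer %||% "D1",
                   config = cfg, files = files)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(mpath)
}

#' Evaluate a simulated (or imported) bundle directory
#'
#' Loads every bundle listed in the manifest and produces the full
#' evaluation: pairwise Dice table against the gold observer, per-observer
#' conformity indices, per-fraction clinical and gold-standard tier
#' classifications, the workflow summary and the outcome matrix.  Reports
#' (delimited tables, a JSON summary, a per-constraint evaluation log and
#' a heat-map PNG) are written to `report_dir` when given.  Plans that
#' fail constraints are results, not errors.
#' @param in_dir directory containing bundles and `manifest.json`.
#' @param report_dir optional directory for report files.
#' @param constraints optional list of [constraint_spec]; default derives
#'   the tier-appropriate constraint set from each patient's prescription.
#' @param quiet suppress progress messages.
#' @return a list with `dsi`, `ci`, `outcomes`, `summary`, `matrix`,
#'   `evaluations` (per-constraint log data frame), `anova`.
#' @export
run_evaluate <- function(in_dir, report_dir = NULL, constraints = NULL,
                         quiet = FALSE) {
  mpath <- file.path(in_dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", in_dir)
  manifest <- jsonlite::fromJSON(mpath, simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  gold_id <- manifest$gold_observer %||% "D1"
  files <- manifest$files
  bundles <- lapply(files, function(fi) read_bundle(file.path(in_dir, fi$path)))
  obs_class <- setNames(vapply(files, function(fi) fi$observer_class %||% "observer",
                               character(1)),
                        vapply(files, `[[`, character(1), "observer"))
  key <- vapply(bundles, function(b) paste(b$patient_id, b$fraction_id, sep = "/"),
                character(1))
  oid <- vapply(bundles, function(b) b$observer_id, character(1))
  if (!any(oid == gold_id)) stop("gold observer '", gold_id, "' bundles missing")

  # contour agreement on bladder + cranially limited bowel
  dsi <- pairwise_dsi(bundles, reference = gold_id,
                      structures = c("Bladder", "Bowel_eval"),
                      benchmark = {
                        phys <- names(obs_class)[obs_class == "physician"]
                        setdiff(phys, gold_id)[1]
                      })
  grp <- attr(dsi, "values")
  anova_res <- if (length(grp) >= 2 && all(lengths(grp) >= 2)) {
    pooled <- split(unlist(grp), rep(sub(" (Bladder|Bowel_eval)$", "", names(grp)),
                                     lengths(grp)))
    tryCatch(anova_oneway(pooled), error = function(e) NULL)
  }

  ci_rows <- list(); outcomes <- list(); eval_rows <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    gold_i <- sel[oid[sel] == gold_id]
    if (length(gold_i) != 1) stop("gold bundle missing for fraction ", k)
    gold_structs <- bundles[[gold_i]]$structures
    for (i in sel) {
      b <- bundles[[i]]
      rx <- b$prescription
      if (is.null(rx)) stop("bundle ", k, "/", b$observer_id, " lacks a prescription")
      cons <- constraints %||% default_constraints(rx)
      if (is.null(b$dose)) stop("bundle ", k, "/", b$observer_id, " lacks dose")
      ci_rows[[length(ci_rows) + 1]] <- data.frame(
        patient_id = b$patient_id, fraction_id = b$fraction_id,
        observer_id = b$observer_id,
        ci = conformity_index(b$dose, get_structure(b, "PTV"), rx$total_gy),
        stringsAsFactors = FALSE)
      clinical <- classify(b$dose, b$structures, cons)
      gold <- gold_overlay_eval(b, gold_structs, cons)
      for (basis in c("clinical", "gold")) {
        tr <- if (basis == "clinical") clinical else gold
        eval_rows[[length(eval_rows) + 1]] <- cbind(
          data.frame(patient_id = b$patient_id, fraction_id = b$fraction_id,
                     observer_id = b$observer_id, basis = basis,
                     stringsAsFactors = FALSE),
          as.data.frame(tr))
      }
      outcomes[[length(outcomes) + 1]] <- fraction_outcome(
        b$patient_id, b$fraction_id, b$observer_id, clinical, gold,
        observer_class = unname(obs_class[b$observer_id]))
    }
    if (!quiet) message("evaluated ", k)
  }
  ci_tab <- do.call(rbind, ci_rows)
  ci_summary <- do.call(rbind, lapply(split(ci_tab, ci_tab$observer_id), function(d)
    data.frame(observer_id = d$observer_id[1], mean = mean(d$ci),
               sd = if (nrow(d) > 1) sd(d$ci) else 0, n = nrow(d),
               stringsAsFactors = FALSE)))
  summary <- aggregate_outcomes(outcomes)
  omat <- outcome_matrix(outcomes)
  evaluations <- do.call(rbind, eval_rows)

  if (!is.null(report_dir)) {
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) write.table(d, file.path(report_dir, f), sep = "\t",
                                     row.names = FALSE, quote = FALSE)
    wt(as.data.frame(dsi), "dsi_table.tsv")
    wt(ci_summary, "ci_table.tsv")
    wt(ci_tab, "ci_per_fraction.tsv")
    wt(evaluations, "evaluations.tsv")
    wt(summary$outcomes, "outcomes.tsv")
    wt(as.data.frame(omat), "outcome_matrix.tsv")
    jsonlite::write_json(
      list(overall = summary$overall, per_class = summary$per_class,
           crosstab = as.data.frame(summary$crosstab),
           anova_p = if (!is.null(anova_res)) anova_res$p_value),
      file.path(report_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    plot_outcome_matrix(omat, file.path(report_dir, "outcome_matrix.png"))
  }
  list(dsi = dsi, ci = ci_summary, ci_per_fraction = ci_tab,
       outcomes = outcomes, summary = summary, matrix = omat,
       evaluations = evaluations, anova = anova_res)
}
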