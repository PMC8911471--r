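# adaptqa

Simulation and quality assurance for **adapt-to-shape online adaptive
radiotherapy** workflows in which non-physician staff (radiation therapists,
trainees) perform the daily recontouring and plan approval, and a
physician-drawn contour set serves as retrospective gold standard.

The package provides an end-to-end synthetic testbed:

* a geometric **pelvic phantom** (bladder, bowel, target) with stochastic
  inter-fraction deformation and per-observer contour noise, calibrated to a
  target Dice similarity index;
* the **adapt-to-shape planning rules** (CTVplan = CTV trimmed to ≤ 3 mm
  bladder depth minus bowel; PTV = CTVplan + 3 mm; Bowel_eval = bowel within
  15 mm above the target), built on an exact anisotropic Euclidean distance
  transform in C++;
* a **conformal dose surrogate** with a tunable conformity index and
  optional organ caps;
* **tiered constraint evaluation** (MET / ACCEPTABLE_VARIATION / FAIL, with
  the conventional- and short-course limits), a **gold-standard overlay**
  re-evaluating each plan on the physician contours, and the three workflow
  dispositions `DELIVERED_OK`, `DELIVERED_SUBOPTIMAL` (silent failure),
  `HALTED_FOR_REVIEW`;
* cohort **simulate → evaluate** drivers with byte-reproducible on-disk
  bundles, manifests with MD5 checksums, TSV/JSON/PNG reports, Dice-ANOVA
  across observer pairs, and conformity-index tables;
* lightweight **DICOM RTSTRUCT/RTDOSE** read/write (explicit/implicit VR
  little endian) and a versioned binary bundle format, so intermediates can
  be inspected with standard tools.

## Key quantities

* **Dice similarity index** between contours A, B:
  `DSI = 2|A ∩ B| / (|A| + |B|)`.
* **Conformity index** (RTOG): `CI = V(dose ≥ 0.95·Rx) / V(PTV)`, counted
  over the whole grid — CI > 1 means dose spill.
* **DVH metrics** `Dmean`, `Dmax`, `D<v>cc`, `D<x>%` with rank-slab
  interpolation at `k = V/v_voxel + 0.5` on descending doses.
* **Pass rates**: clinical (observer-basis), gold-standard
  (physician-basis), and the workflow **safety rate** = fractions delivered
  fine or correctly halted; safety ≥ gold pass rate holds by construction.
  Rates round half-even to one decimal.

See the vignette (`vignettes/adaptqa-methods.Rmd`) for the model details,
conventions, and known limitations of the generator.

## Worked example

```r
library(adaptqa)

## phantom on the default clinical grid (1.5 x 1.5 x 3 mm voxels)
grid <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(80, 80, 50))
pc <- generate_planning_case(anatomy_params(seed = 1), grid)
b  <- apply_planning_rules(pc)

max_penetration_mm(get_structure(pc, "CTV"), get_structure(pc, "Bladder"))
#> [1] 10.5
max_penetration_mm(get_structure(b, "CTVplan"), get_structure(pc, "Bladder"))
#> [1] 3

## prescription and synthetic conformal dose
rx <- prescription_spec(2, 25)
rx
#> prescription: 2 Gy/fx x 25 = 50 Gy (CONVENTIONAL)
ptv  <- get_structure(b, "PTV")
dose <- synthesize_dose(ptv, dose_model_params(rx$total_gy, seed = 11))

## tiered constraint evaluation
res <- classify(dose, b$structures, default_constraints(rx))
res
#>    structure  metric value_gy ideal_gy acceptable_gy                 tier
#> 1    Bladder   Dmean 16.24295       40            44                  MET
#> 2 Bowel_eval D0.03cc 51.23126       50            55 ACCEPTABLE_VARIATION
plan_tier(res)
#> [1] "ACCEPTABLE_VARIATION"
conformity_index(dose, ptv, rx$total_gy)
#> [1] 1.152776

## an observer recontours the bladder with 1.2 mm noise
prof <- observer_profile("T1", "therapist", noise_amplitude_mm = 1.2)
ob <- generate_observer_contours(pc, prof, seed = 7)
dice(get_structure(pc, "Bladder"), get_structure(ob, "Bladder"))
#> [1] 0.9882319
```

## A full cohort run

```r
cfg <- default_experiment_config(master_seed = 20220223)  # 10 patients x 2 fractions x 6 observers
run_simulate(cfg, "sim")            # writes bundles + manifest.json (MD5s)
ev <- run_evaluate("sim", "report") # writes TSV/JSON/PNG reports

ev$summary$overall$clinical$pass_rate_pct   # observer-basis pass rate
ev$summary$overall$gold$pass_rate_pct       # gold-standard pass rate
ev$summary$overall$safety$safety_rate_pct   # workflow safety rate
mean(ev$ci_per_fraction$ci)                 # cohort mean conformity index (~1.2)
```

The same configuration and master seed reproduce byte-identical bundles.
A thin command-line wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/adaptqa simulate --default --seed 20220223 --out sim
Rscript inst/cli/adaptqa evaluate --in sim --report report
```

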