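---
title: "adaptqa: methods and modelling notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{adaptqa: methods and modelling notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptqa)
```

# Purpose

`adaptqa` is a simulation and quality-assurance toolbox for *adapt-to-shape*
online adaptive radiotherapy workflows on MR-guided linear accelerators, in
which the daily recontouring and plan approval may be performed by
non-physician staff (radiation therapists, trainees) while a physician-drawn
contour set acts as a retrospective gold standard.  The package asks the
quantitative question behind that workflow design: *if observers with
class-specific contouring variability adapt the plan each day, how often does
the adapted plan pass the clinical dose constraints, how often would it have
passed on the gold-standard anatomy, and how often is a deficient plan
actually delivered?*

Everything is synthetic and self-contained: a geometric pelvic phantom,
stochastic inter-fraction deformation, stochastic observer contour noise, a
conformal dose surrogate, tiered constraint evaluation, and cohort-level
reporting, plus DICOM-subset and bundle I/O so the intermediate products can
be inspected with standard tools.

# The phantom

`generate_planning_case()` builds a three-structure pelvic phantom on a voxel
grid (default 80 × 80 × 50 voxels at 1.5 × 1.5 × 3 mm; all coordinates are in
mm, and the grid origin is the *centre* of voxel (1,1,1)):

* **Bladder** — an ellipsoid (default semi-axes 30 × 25 × 22 mm).
* **CTV** (clinical target volume) — an ellipsoid placed against the
  posterior bladder surface so that it *penetrates* the bladder by a
  prescribed depth (default 10 mm).  The penetration is realised by a
  bisection on the target centre position against the measured
  `max_penetration_mm()`, so the requested depth is recovered to within a
  voxel diagonal.
* **Bowel** — a helical tube (default radius 10 mm) winding above the
  bladder, with a hard 3 mm clearance from the bladder enforced by carving
  with the bladder's Euclidean distance map.

Patient-to-patient variation comes from seeded relative jitter on the organ
sizes and positions (`jitter_frac`; the cohort driver uses 6 %), so no two
patients share an anatomy while each seed remains exactly reproducible.
Smooth Gaussian random fields (`smooth_noise_field()`: white noise on a
coarse lattice, trilinearly interpolated, then standardised to zero mean and
unit variance) drive the deformation and observer-noise models below.  A
fit check rejects grids that cannot hold the
anatomy with 5 mm clearance instead of silently truncating structures.

## Per-fraction deformation

`generate_fraction()` warps the planning anatomy with a smooth random
3-component displacement field (amplitude in mm divided by √3 per component,
default correlation length 30 mm).  Organs at risk deform freely but a
rejection loop bounds the volume change (×0.7 guard); the CTV is moved
*rigidly* (translated by the mean displacement over the target) so target
volume is conserved up to resampling jitter.  Voxels claimed by both bladder
and bowel after deformation are resolved by distance (nearer organ wins),
preserving disjointness.  Amplitude 0 is exactly the identity.

## Observer contour noise

`generate_observer_contours()` models an observer as a threshold on the
signed distance function (SDF) of the true structure:

\[ \text{contour} = \{\, \mathrm{sdf}(x) \le a\,F(x) + b \,\} \]

with `F` a standardised smooth field, `a` the noise amplitude (mm) and `b` a
systematic bias (mm; positive = over-contouring).  Amplitude 0 and bias 0
reproduce the truth voxel-exactly.  Because the achieved Dice coefficient
depends on structure size and grid resolution as well as `a`,
`calibrate_observer_noise()` inverts the relationship by bisection: given a
target Dice (e.g. 0.97 for an experienced therapist) it returns the
amplitude that achieves it in expectation on *this* phantom.

# Planning rules

`apply_planning_rules()` encodes the adapt-to-shape contouring protocol:

* **CTVplan** = CTV, trimmed so that it reaches at most 3 mm *into* the
  bladder (`trim_to_depth()`, depth = the organ-interior Euclidean distance),
  then minus bowel.  The rule order matters and is fixed: trim, then
  subtract.
* **PTV** = CTVplan expanded isotropically by 3 mm (`expand_mask()`,
  inclusive: distance ≤ margin).  The PTV is deliberately **not** re-trimmed
  against the organs — the margin exists to cover geometric uncertainty, so
  it may overlap them.
* **Bowel_eval** = bowel cropped (inclusively) to at most 15 mm above the
  superior extent of the CTV, the region where bowel dose is
  protocol-relevant.

All mask algebra rides on an exact anisotropic Euclidean distance transform
(Felzenszwalb–Huttenlocher, implemented in C++), so expansions and trims are
voxel-exact rather than approximate morphological operations.

# The dose surrogate

`synthesize_dose()` produces a conformal dose distribution without an
optimiser or beam model.  With `sdf` the PTV signed distance (negative
inside):

\[ D(x) = \mathrm{Rx} \cdot \sigma\!\left(\frac{m - \mathrm{sdf}(x)}{s}\right),
   \qquad m = \text{bulge} + s \ln 19 \]

a logistic fall-off with scale `s` (`falloff_mm`, default 3 mm).  The offset
`m` is chosen so that the 95 % isodose sits `bulge_mm` *outside* the PTV
surface: **`bulge_mm` is the package's conformity knob**, directly
controlling the RTOG conformity index of the synthetic plans.  On top of
this, a smooth multiplicative hotspot field adds realistic heterogeneity; it
is weighted by \((D/\mathrm{Rx})^8\) so it perturbs the high-dose region
without dilating the penumbral 95 % isodose surface one-sidedly.  Finally
the dose is normalised so the **median** PTV dose equals the prescription
(median, not D95: normalising to a tail statistic makes the whole
distribution chase the coldest noise blob).  Optional per-organ caps clamp
dose inside a mask, emulating an optimiser that respects an OAR objective it
can "see".

The defaults (`bulge_mm = 2.5`, `hotspot_frac = 0.02`) were fixed by
design-time calibration so that the default cohort's mean conformity index
lands near 1.2, inside the 1.0–1.3 regime reported for clinical
adapt-to-shape pelvic plans.

## How failures arise

In `adapt_plan()` the optimiser-surrogate caps the dose inside the
*observer's own* `Bowel_eval` just below the ideal limit.  Consequently the
clinical (observer-basis) evaluation essentially always passes the bowel
constraint — as a real plan approved on those contours would.  The
gold-standard overlay (`gold_overlay_eval()`) then re-evaluates the *same*
dose on the physician's contours: where the observer under-contoured bowel
near the target, gold bowel voxels sit inside the PTV at prescription-level
dose and the D0.03cc constraint can fail.  This reproduces the clinically
interesting event class: the *silent* failure, a plan that is delivered
(clinical pass) but is deficient on the gold standard
(`DELIVERED_SUBOPTIMAL`).  With the default constraint sets only the
conventional-fractionation patients are close enough to the bowel limit for
this to occur.

# Evaluation conventions

* **DVH metrics** (`dose_metric()`): `"Dmean"`, `"Dmax"`, `"D<v>cc"`,
  `"D<x>%"`.  Dose-at-volume sorts structure doses descending and
  interpolates at rank \(k = V/v_\text{vox} + 0.5\) (the +0.5 treats each
  voxel as a slab centred on its rank), clamped to the ends.  Requesting a
  volume beyond the structure volume is an error, not an extrapolation.
* **Conformity index** (`conformity_index()`): RTOG definition,
  \(\mathrm{CI} = V_{\ge 0.95\,\mathrm{Rx}} / V_\mathrm{PTV}\), with the
  95 % threshold *inclusive* and \(V_{\ge}\) counted over the **whole grid**
  (not just inside the PTV) — CI > 1 means spill.
* **Tiers**: a constraint value ≤ ideal is `MET`, ≤ acceptable is
  `ACCEPTABLE_VARIATION`, otherwise `FAIL`; boundaries are inclusive toward
  the better tier.  A plan's tier is the worst structure tier.
* **Constraint sets** (`default_constraints()`): conventional fractionation
  (1.8–2 Gy/fraction) — bladder Dmean 40/44 Gy, bowel D0.03cc 50/55 Gy;
  short course (5 Gy/fraction) — bladder Dmean 22/24 Gy, bowel D0.03cc
  27.5/30 Gy.  Any other dose per fraction has no defined tier and is
  rejected.
* **Dispositions**: clinical `FAIL` → `HALTED_FOR_REVIEW` (the workflow
  catches it); otherwise gold `FAIL` → `DELIVERED_SUBOPTIMAL` (silent
  failure); otherwise `DELIVERED_OK`.  The *safety rate* counts fractions
  that are either delivered fine or halted; by construction it can never be
  below the gold-standard pass rate.
* **Rates** are percentages rounded half-even to one decimal
  (73/80 = 91.25 → 91.2), the convention used in clinical reporting.
* **Statistics**: observer-agreement Dice similarity indices are compared
  across observer pairs with a classical one-way ANOVA
  (`anova_oneway()`, a thin wrapper over the pooled-variance F test).

# Reproducibility machinery

Every stochastic stage takes an explicit seed.  Cohort runs derive
per-(patient, fraction, observer) seeds from the master seed with
`derive_seed()`, a multiply-add modular hash over the label bytes that is
exact in double arithmetic and always yields a valid seed below 2³¹.  The
same configuration and master seed therefore reproduce byte-identical bundle
files, which `run_simulate()` proves by writing MD5 checksums into
`manifest.json`.

# Known limitations of the generator

* The dose surrogate has no beam geometry: fall-off is isotropic around the
  PTV, there are no entrance/exit dose streaks, and OAR sparing is modelled
  as a hard cap rather than a trade-off.
* Observer noise is a stationary SDF threshold; real observers make
  structured, slice-wise, anatomy-driven errors, and their disagreement is
  not spatially stationary.
* Deformation is a free-form smooth field with a rigid target; it does not
  conserve tissue, model bladder filling as a physical process, or couple
  organ motions.
* Because observer classes are given distinct noise amplitudes by
  construction, the cohort ANOVA on Dice indices is essentially always
  strongly significant — unlike a real observer study, where class
  differences may be undetectable.  The machinery, not the p-value, is the
  point.

These simplifications are deliberate: the package is a testbed for workflow
*logic* (rules, constraints, overlays, dispositions, reporting), for which
the geometry and dosimetry only need to be plausible, controllable, and
exactly reproducible.

# A minimal end-to-end run

```{r cohort, eval = FALSE}
cfg <- default_experiment_config(master_seed = 20220223)
run_simulate(cfg, "sim")
ev <- run_evaluate("sim", "report")
ev$summary$overall$clinical$pass_rate_pct
ev$summary$overall$gold$pass_rate_pct
ev$summary$overall$safety$safety_rate_pct
mean(ev$ci_per_fraction$ci)
```

(Not evaluated here: the default cohort — 10 patients × 2 fractions × 6
observers — takes a couple of minutes.)
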