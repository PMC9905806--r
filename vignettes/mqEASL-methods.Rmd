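---
title: "Volumetric tumor response and survival-based cutoffs: models and methods"
author: "mqEASL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric tumor response and survival-based cutoffs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqEASL)
```

# Scope

`mqEASL` implements a quantitative, volumetric alternative to
diameter-based response grading for hepatocellular carcinoma treated with
transarterial chemoembolization, and the survival machinery needed to
(a) derive the volumetric responder cutoff from outcome data and
(b) compare the volumetric marker head-to-head with the diameter marker
as a predictor of overall survival. Because no patient-level imaging or
survival data are distributable, the package carries first-class
generators that emulate both input types with known ground truth; all
quantitative claims made by the test suite are claims about those
synthetic conditions.

# Viable tumor quantification

The imaging unit works on co-registered arterial-phase enhanced and
unenhanced volumes sharing one grid (registration is a precondition,
checked through shape/spacing equality, not a feature). The steps are:

1. **Enhancement map**: voxelwise `enhanced − unenhanced`. Negative
   values are legitimate (e.g. embolized, hypodense tissue).
2. **Parenchymal threshold**: the mean of the enhancement values at
   healthy-parenchyma reference points. Each point contributes the mean
   over a cubic neighborhood of configurable radius (default 1, a
   3×3×3 block; radius 0 reproduces literal single-voxel sampling). The
   neighborhood default is a noise-robustness choice: a single voxel of
   a clinical image is a high-variance sample of parenchymal
   enhancement, and a 27-voxel mean keeps the threshold stable without
   materially widening the sampled region. At least three points are
   required; neighborhoods are clipped at the volume boundary.
3. **Viable segmentation (Seg2)**: voxels inside the whole-tumor mask
   (Seg1) whose enhancement is *strictly greater* than the threshold.
   The strict inequality is deliberate: at equality a voxel enhances
   exactly like parenchyma and carries no evidence of viability.
4. **Viable tumor volume**: `voxel count × voxel volume`, reported in
   cm³; anisotropic spacing is supported, with the voxel volume taken as
   the product of the per-axis spacings.

Whole-tumor segmentation itself is interactive in practice and is
therefore an *input* here; the phantom generator supplies it in tests.
NIfTI is the interchange format (spacing from the header pixdims);
reference points travel as a CSV of 0-based voxel coordinates.

# Response classification

All change quantities are percentages on [−100, ∞); fractions are never
accepted or returned at the API boundary, which removes a whole class of
unit bugs. Diameter change (DC) and viable-volume change (VC) use the
same formula, `(followup − baseline)/baseline × 100`, and the cube-law
expected volume change is `EVC = ((1 + DC/100)³ − 1) × 100`.

mRECIST categories follow the standard precedence: a new intrahepatic
lesion forces PD regardless of anything else; complete disappearance of
target enhancement gives CR; DC ≥ +20% gives PD; DC ≤ −30% gives PR; SD
otherwise. Responders are CR ∪ PR. Progression is assessed against
baseline — this is a single-follow-up design, so there is no nadir to
track.

The volumetric (mqEASL) rule is a pure dichotomy: responder iff
VC ≤ cutoff (inclusive; default −57%) and no new lesion. No separate CR
tier is modeled on the volumetric side, and no +20% progression bar is
applied to VC: the marker enters the survival models as the plain
responder indicator.

Agreement between the two classifications is summarized by Cohen's
kappa with its large-sample (Fleiss–Cohen–Everitt) confidence interval,
banded qualitatively at <0.4 / 0.4–0.75 / >0.75, and a McNemar test on
the discordant cells — chi-square without continuity correction when at
least 25 pairs are discordant, exact binomial otherwise. When both
margins are fully concentrated kappa is undefined and reported as
degenerate rather than silently dropped.

# The survival-based cutoff

The cutoff derivation models the log relative hazard of death as a
smooth function of VC:

* **Basis.** A restricted (natural) cubic spline in truncated-power
  form: the identity plus k−2 nonlinear terms built to be linear beyond
  the boundary knots, normalized by the squared outer-knot spread. With
  the default k = 4 this gives 3 regression columns.
* **Knots.** Empirical quantiles 0.05/0.35/0.65/0.95 of the observed VC
  — the standard placement for four knots. Knot placement is
  configurable, and duplicate quantiles (possible because VC has a
  point mass at −100, see below) are collapsed.
* **Fit.** Cox partial likelihood with Efron tie handling, spline terms
  as the only covariates. Patients with new lesions are excluded from
  the derivation (they are non-responders by fiat downstream, so their
  VC carries no decision information here).
* **Reference.** "Hazard ratio equals 1" needs a comparator. The
  package uses the median VC of the records entering the fit; the
  reference is configurable, and by construction HR(reference) = 1.
* **Crossing.** The log-HR curve is sampled on a 0.5-point grid over
  the observed VC range, sign changes are bracketed and polished with
  `uniroot` to 10⁻³ percentage points. When the hazard is monotone in
  VC — the expected clinical shape: less volume reduction, more risk —
  there is exactly one crossing. If the fitted curve wiggles through 1
  several times, the crossing on the protective boundary (steepest
  hazard *rise* with increasing VC) is selected and all roots are
  reported. A curve that never crosses 1 in range raises a typed
  `noCrossingError` carrying the sampled curve for inspection.

One structural consequence is worth stating plainly: with a monotone
fitted curve, the HR = 1 crossing *is* the reference value, i.e. the
cohort median VC. The derivation is still far from vacuous — the spline
fit, its confidence band, and the root search establish that the hazard
actually rises through 1 there and how steeply — but "the cutoff" should
be read as "the VC value the cohort-median reference pins to HR = 1,
validated against the fitted hazard shape". The recovery tests exercise
the full chain (knot placement, basis, Cox fit, curve sampling, root
finding) against cohorts whose median VC is planted by construction.
Whether knots and reference should be refit on a validation cohort is
left to the caller; the pipeline refits per cohort by default.

# Marker comparison

* **Split.** Random 7:3 training/validation partition
  (`round(0.7 n)` training), seeded.
* **Models.** Pretreatment covariates — metastasis (binary), portal
  vein tumor thrombus (binary), subsequent treatment (a single ordinal
  0–3 term: none / locoregional / systemic / combined) — are screened
  univariately (default p < 0.05, configurable; if none survive, all
  three enter) and combined with one response marker: Model 1 carries
  the mRECIST responder, Model 2 the mqEASL responder. The ordinal
  coding of subsequent treatment is intentional: it matches the printed
  linear predictors this comparison targets.
* **Discrimination.** Harrell's C (ties in the predictor count ½,
  infinitesimal-jackknife SE, via `survival::concordance`) and a
  time-dependent AUROC of the cumulative-cases / dynamic-controls type
  with inverse-probability-of-censoring weights from a Kaplan–Meier fit
  of the censoring distribution. Horizons default to 6, 12 and 24
  months. The AUROC CI is a seeded percentile bootstrap (default 500
  resamples; tests and the pipeline default use fewer). Without
  censoring the estimator reduces exactly to the empirical AUC between
  events-by-t and survivors-past-t, which is how it is validated.
* **Calibration.** Predicted survival from the Breslow baseline of the
  training fit, `S(t|x) = exp(−H0(t) e^lp)`, grouped into predicted-risk
  tertiles (binning is not prescribed anywhere authoritative; tertiles
  keep ~30 subjects per group at the cohort sizes involved), against
  the group-wise Kaplan–Meier estimate with log-log CIs. Groups with
  nobody at risk at the horizon are flagged rather than dropped.
* **Medians.** KM median OS with Brookmeyer–Crowley log-log CIs; when
  the curve never reaches 0.5 the median and open bounds are `NA`.

# The synthetic-data generators

**Phantoms.** A voxelized ellipsoid tumor in homogeneous parenchyma; a
concentric inner ellipsoid scaled by `(1 − viableFraction)^(1/3)` is
necrotic so the viable shell holds the requested volume fraction.
Default intensities (arbitrary units): parenchyma 100 unenhanced,
enhancing by 80; viable tumor enhancing by 120; necrosis by 10. The
ordering viable > parenchyma > necrotic is enforced by the class
validity — it is what makes the parenchymal threshold discriminative by
construction. Gaussian noise is added independently to each volume.
Truth (viable mask, exact voxel-count VTV) is returned alongside, plus
three reference points placed near grid corners. The phantoms model
first-order contrast structure only: no texture, partial-volume
blurring, motion, or bias fields, so quantification accuracy on
phantoms is an upper bound on clinical accuracy.

**Cohorts.** One row per patient on the cohort CSV schema. Design
choices, with their rationale:

* Covariate prevalences default to the pooled observed case mix:
  metastasis 0.20, PVTT 0.18, subsequent treatment (52/29.5/9.25/9.25)%.
* Baseline diameter sums are log-normal (median 7 cm); baseline volumes
  follow a sphere-with-scatter relation `π/6 d³ × e^ε`.
* DC is Gaussian (sd 25 points, clipped to [−100, 100]); complete
  disappearance (probability 0.18) forces DC = VC = −100; new lesions
  (probability 0.12) are independent.
* VC follows the empirical relation `VC = 1.88 EVC + 69.75 + N(0, 50)`,
  clipped at −100. The residual sd of 50 was fixed from two observed
  anchors: the single-patient worked example, where the cube-law
  expectation (−80.2%) and the measured change (−40.8%) differ by ~40
  points, and the requirement that mRECIST/mqEASL agreement land in the
  observed "moderate" kappa band (generated cohorts give κ ≈ 0.70).
  The clip produces a genuine point mass at VC = −100 (roughly a third
  of patients under the defaults), which is why knot deduplication
  exists.
* The log hazard is
  `β_m·met + β_p·pvtt + β_s·subs + g(VC)` with Model-2-scale defaults
  (1.88, 0.92, −0.36) and either `g(VC) = 0.02 (VC − crossing)`
  (`hazardModel = "spline"`) or a responder-level effect of −1.41
  (`hazardModel = "responder"`). Event times come from inverse-transform
  sampling on a piecewise-constant baseline (default: exponential,
  median 20 months).
* The planted HR = 1 crossing (default −57) is enforced by solving the
  DC location so the *population median* of VC equals the crossing —
  numerically, through the exact mixture integral over the DC draw, the
  VC noise and the clip, not by the naive quantile transform (EVC's
  convexity would otherwise bias the planted median by several points).
* Censoring is exponential (0.006/month) with an administrative horizon
  of 96 months, fixed to give the observed ~18% censored fraction.
* Every generator is a pure function of spec + seed, restores the
  caller's RNG state, and is bit-reproducible.

What the generators do *not* emulate: correlated covariates, cohort
drift between training and validation, measurement error in diameters,
informative censoring, or non-proportional hazards. Passing tests show
the estimators recover planted structure under the stated conditions —
not that clinical cohorts satisfy those conditions.

# Numerical choices and degenerate inputs

* Root tolerance 10⁻³ percentage points on a 0.5-point bracketing grid.
* Strict `>` at the enhancement threshold; an all-equal map segments to
  empty.
* `percentChange` rejects non-positive baselines (the change is
  undefined, not infinite).
* Spline fits require ≥ 1 event and finite coefficients; separation in
  Cox fits is reported as an error, not returned as a huge coefficient.
* Knot placement requires ≥ 20 distinct VC values; duplicate quantile
  knots are collapsed.
* Kappa with chance agreement 1 is reported as degenerate (`NA` plus a
  flag).
* Fewer than 10 events per covariate in a multivariate Cox fit warns
  (the events-per-variable rule of thumb) but does not stop.

# Problem sizes used by the test suite

The suite validates recovery at sizes chosen to make the Monte Carlo
noise small relative to the tolerance being asserted: 50 cohorts of
n = 500 for cutoff recovery (median absolute error ≤ 8 points),
n = 2000 for Cox coefficient recovery (±0.25), n = 200 for the EVC–VC
slope (±0.15), 50 cohorts of n = 300 for the directional Model 1 vs
Model 2 comparison, and 48³ phantoms for quantification (2% noiseless,
5% at noise sd = 5% of contrast). These are the package's documented
reference conditions; rerunning at larger n only tightens them.

# Known limitations

* The cutoff has no confidence interval (none is defined for it here),
  and optimal-cutpoint approaches (e.g. maximally selected rank
  statistics) are intentionally out of scope.
* The imaging unit assumes co-registered phases and takes Seg1 as
  given; DICOM ingestion, registration and interactive segmentation are
  out of scope.
* Multiple target lesions are handled by summing per-lesion viable
  volumes, mirroring the diameter-sum convention; this is an assumption,
  not an observed rule.
* The C-index SE is analytic; a bootstrap alternative would be easy to
  add but is not implemented.
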