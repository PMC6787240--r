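---
title: "Methods: biparametric FET-PET/ADC lesion analysis and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biparametric FET-PET/ADC lesion analysis and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetadc)
```

## The measurement model

`fetadc` quantifies a focal brain lesion on a co-registered pair of 3D
volumes: an amino-acid PET volume in SUV units and an ADC map in
10⁻⁶ mm²/s. Both are assumed co-registered in one RAS world frame (as
acquired on a hybrid scanner), with the mid-sagittal plane at a known
world *x* (0 for phantoms, user-supplied otherwise). All voxel indices
are 0-based; voxel centres carry the coordinates.

The per-patient read-out is produced in five steps:

1. **Hot-component search.** The SUV volume is thresholded at
   `fraction × max` over the brain mask (`fraction = 0.80`, the IC80
   convention; isocontour thresholds in the 40–90% range are common in
   PET segmentation, and 80% deliberately confines the VOI to the
   metabolically most active core). Supra-threshold voxels are split
   into 26-connected components. The component containing the global
   maximum always survives, so the candidate list is never empty.
2. **Prominent-lesion selection.** Candidates are ranked by maximum
   uptake, then voxel volume, then (optionally) distance of the
   component maximum to a user-supplied reference point such as the
   resection cavity. The ordering is deterministic; ties at a component
   maximum resolve to the lexicographically smallest index triple.
3. **Local isocontour.** The selected component is re-thresholded at
   `fraction` times *its own* maximum, so a dimmer secondary lesion
   would still carry a true 80% isocontour of its own peak rather than
   inheriting the global one. By construction every VOI voxel value
   lies within `fraction` of the VOI maximum — which pins
   SUV80mean/SUVmax into [0.8, 1] and makes the two nearly collinear
   across a cohort.
4. **Transfer and margin adaptation.** The VOI is mapped to the ADC
   grid by pushing each candidate ADC voxel centre through the ADC
   affine and the inverse SUV affine and keeping it if it lands inside
   a VOI voxel (nearest neighbour; an empty result signals
   mis-registration and is an error, not an empty measurement). Voxels
   with ADC ≥ 2400 (default; free water is ≈ 3000, tumour tissue well
   below) or inside an explicit exclusion mask are removed. Losing more
   than half the VOI — or all of it — indicates a mis-placed VOI and
   raises an error.
5. **Background and ratios.** On the representative slice (highest mean
   uptake within the VOI; ties resolve to the inferior-most slice) the
   in-slice VOI centroid is reflected across the midline and a disk of
   equal in-plane area is placed there, clipped to the brain mask
   (errors if more than 25% of its area is lost or if it touches the
   lesion VOI). The same region, transferred to the ADC grid, provides
   the ADC background, so SUV-BG and ADC-BG come from one anatomical
   locus. The ratios are TBRmax = SUVmax/SUV-BG,
   TBR80mean = SUV80mean/SUV-BG, rADCmean = ADCmean/ADC-BG.

Choices the underlying workflow leaves open — the connectivity rule,
the seeding of the isocontour tool, the exact shape of the "similar
size" contralateral region, and how marginal adaptation is performed —
are fixed here as: 26-connectivity (the permissive standard for 3D
hot-spot masks), seed at the in-mask maximum, a geometric mirror disk
of matched area, and a hard ADC cutoff plus optional exclusion mask.
They are this package's decisions, not a claim about how any particular
clinical workflow implemented them.

## Cohort statistics

- **Group comparisons** use Student's pooled-variance two-sample t-test
  (`independent_t_test`, wrapping `stats::t.test(var.equal = TRUE)`),
  reported as MD ± SE — the layout used in clinical summaries whose
  printed SEs are consistent with pooling. Welch's variant is available
  via `var_equal = FALSE`.
- **ROC analysis** (`empirical_roc`) computes the AUC as the normalised
  Mann–Whitney statistic with ties counted ½. The standard error is the
  DeLong structural-components estimator; with sample variances on
  *n − 1* denominators it coincides *exactly* with the grouped
  delete-one jackknife (the test suite asserts agreement to 1e−10,
  and cross-checks against pROC). Classes with a single subject
  contribute zero variance, matching the jackknife's vanishing
  (m−1)/m factor. The 95% CI is formed on the logit scale and clipped
  to [0, 1] — a boundary-safe choice made here because no CI method is
  canonical for small samples; the p-value against AUC = 0.5 uses the
  normal approximation.
- **Correlated-curve comparison** (`compare_roc`) is the DeLong test:
  the covariance of the structural components enters the variance of
  the AUC difference; in unpaired mode variances add. Identical curves
  return difference 0 with p = 1 rather than 0/0.
- **Youden cutoff** (`youden_cutoff`) scans midpoints of consecutive
  sorted unique scores plus one candidate beyond each extreme; ties
  resolve toward higher specificity, then the larger cutoff —
  specificity is favoured because the clinical cost of a false-positive
  recurrence call is re-operation.
- **The biparametric rule** (`classify_biparametric`) is the step-wise
  binary model: each marker is evaluated separately and one marker
  above threshold classifies as recurrence. Thresholds are strict
  (`>`): TBRmax > 2 (the clinically established FET cutoff) and
  ADCmean > 1254 by default.
- **The OR-rule ROC envelope** (`bivariate_roc`): a binary rule has one
  operating point, not a curve, so a full ROC for the marker pair needs
  a construction. We sweep all threshold pairs, collect the achievable
  (1 − specificity, sensitivity) points, and integrate the staircase
  `f(u) = max{sensitivity achievable with 1 − specificity ≤ u}`. For
  tie-free scores with a non-informative second marker this reduces
  exactly to the univariate Mann–Whitney AUC, and it dominates both
  univariate AUCs; with heavily tied scores the ½-credit convention of
  the Mann–Whitney statistic has no deterministic-rule counterpart, so
  dominance is only guaranteed tie-free. The envelope SE comes from a
  seeded bootstrap over subjects, stratified by group (default 2000
  resamples). This envelope is a documented construction of this
  package; a published bivariate AUC need not be reconstructable from a
  binary rule, and no attempt is made to force agreement.
- **Diagnostic measures** report confusion counts and proportions;
  ratios with zero denominators are `NA`, never 0. (Published
  predictive values sometimes assume a non-cohort prevalence; the
  package always reports cohort-empirical values.)

## The phantom generator

No patient images accompany the published summaries this package is
calibrated against, so validation runs on digital phantoms
(`phantom_spec`, `render_phantom`, `generate_cohort`). A phantom is:

- an ellipsoidal "brain" (default semi-axes 55 × 60 × 50 mm) on a
  64 × 64 × 48 grid at 2 × 2 × 2.5 mm — anisotropic like clinical PET
  grids and small enough for seconds-scale rendering; zeros outside;
- background SUV and ADC levels with Gaussian voxel noise. The SUV
  noise field is spatially smoothed (separable Gaussian, σ = 1.5
  voxels) because reconstructed PET noise is strongly correlated after
  filtering; ADC noise is left white. Default SDs: 0.05 SUV, 60 ADC —
  realism choices, since the emulated acquisition reports no noise
  model;
- two CSF spheres (ADC 3000, SUV 0.2 — plausible physiology) placed so
  the default lesion and its mirror stay clear of them;
- one hot lesion with radial profile
  `bg + (peak − bg)·exp(−0.5 (r/σ)^γ)`, centre snapped to a voxel
  centre so the noise-free maximum is attained exactly. Inside the hot
  core — where the noise-free uptake reaches 80% of the peak — the ADC
  is drawn from the lesion distribution (per-voxel SD 100); a one-voxel
  partial-volume shell around the core is included, because a
  measurement VOI whose boundary wobbles with noise samples tissue at
  the contour that is lesion, not healthy background. Without the
  shell, boundary contamination biases extracted ADCmean asymmetrically
  (captured outside voxels carry background ADC; excluded inside
  voxels cause no offsetting error).

### Group calibration

`group_calibration` fixes, per diagnostic group, the between-patient
distributions of target TBRmax and hot-core ADCmean, the background
levels, and the target IC80 mean/max uptake ratio. The packaged
reference calibrations (`default_calibrations()`) use published group
means (ADCmean 1313 vs 1029; TBRmax 3.18 vs 2.09; backgrounds
0.94/768 REC, 1.11/755 PTRE; TBR80mean/TBRmax ratios 2.75/3.18 and
1.80/2.09). Per-group SDs are not published, so both groups share the
pooled SD implied by the printed MD ± SE of the two-sample comparison:
`sd = md_se / √(1/n₁ + 1/n₂)` (`calibrate_from_summary`; 251.2 for ADC,
1.242 for TBR at n = 32/10). This pooled-variance reconstruction is a
modelling assumption, flagged as such, not a recovered property of the
original cohort.

Three sampling details matter:

- **Truncation with moment matching.** Target TBRmax is drawn from a
  normal truncated below at 1.4. A floor is needed because an 80%
  isocontour only closes inside the brain when TBR > 1/0.8 = 1.25;
  1.4 leaves the threshold ≈ 2 noise SDs above background. With the
  large reconstructed SD (1.242), naive truncation would inflate the
  PTRE mean by ≈ 24%, so the truncated-normal *location* is solved
  (by `uniroot` on the closed-form truncated mean, tolerance 1e−10)
  such that the post-truncation mean equals the calibration mean
  exactly. The cost is a narrower realised spread for the PTRE arm
  (≈ 0.58 instead of 1.242) — the mean is treated as the non-negotiable
  calibration quantity, the dispersion as the adjustable one.
- **Profile-shape calibration.** For a generalized-Gaussian lesion the
  continuum IC80 mean/max ratio has the closed form implemented in
  `ic80_mean_max_ratio` (an incomplete-gamma expression independent of
  σ and of the background level). The exponent γ is solved per patient
  (`profile_exponent_for_ratio`) so that this ratio equals the group's
  published TBR80mean/TBRmax ratio; on the default grid the discrete
  ratio tracks the continuum value to a few tenths of a percent.
- **Seeding.** Every cohort is driven by one master seed; per-patient
  spec seeds and render seeds are drawn from it, so cohorts are fully
  reproducible and the truth values (drawn TBRmax, drawn core ADCmean)
  are recorded alongside the measurements.

### What the phantom does and does not emulate

Emulated: hot-lesion contrast over a quiet background, correlated PET
noise, CSF structures that margin adaptation must remove, a guaranteed
contralateral mirror position, co-registered grids, and group-level
metric distributions calibrated to published summaries. Not emulated:
anatomy (no tissue atlas, no grey/white structure), PET point-spread
and partial-volume effects beyond the ADC shell, Rician ADC noise,
registration error, motion, multifocal disease (a multi-lesion option
exists solely to exercise prominent-lesion selection). Passing the
phantom suite therefore validates the *measurement pipeline* —
segmentation geometry, transfer, background mirroring, ratio algebra,
statistics — not the clinical discriminability of the markers on real
patients.

## Validation design and problem sizes

The test suite asserts, among others:

- exact recovery on zero-noise phantoms (TBRmax, ADCmean, rADCmean to
  numerical precision; "exact" bounded at 1e−6 where the lesion-profile
  tail reaches the mirrored ROI);
- calibration recovery on a 200-per-group cohort at the default
  64 × 64 × 48 resolution: pipeline-extracted group means of ADCmean,
  TBRmax, rADCmean and TBR80mean (and the group differences) within 3
  Monte-Carlo SEs of the calibrated values, with an extra 2% slack
  where a mean of per-patient ratios is compared against a printed
  ratio of group means — a few minutes on one CPU;
- oracle equivalence on ≥ 100 random small instances each: AUC vs
  brute-force pair counting, DeLong variance vs grouped jackknife,
  Youden vs an ε-scan, the OR-rule envelope vs exhaustive threshold
  enumeration, and isocontour VOIs vs an independent fixpoint-dilation
  labelling of the supra-threshold set;
- structural properties: IC80 pinning, cohort correlation of SUV80mean
  with SUVmax ≥ 0.99, OR-rule sensitivity/specificity dominance,
  monotone-transform invariance of AUC and Youden J.

`scripts/acceptance.R` re-runs the 200-per-group recovery from scratch
with a caller-supplied seed and writes the eight recovered quantities
as JSON.

## Known limitations

- The PTRE TBR sampling distribution is strongly truncated; its
  realised SD is well below the nominal pooled SD (see above). Cohort
  spreads of PTRE TBRmax are therefore not calibrated, only the mean.
- The pooled-SD reconstruction assumes equal group variances; if the
  original groups differed, the phantom dispersions differ from the
  original cohort's.
- Nearest-neighbour transfer is appropriate for the small grid-spacing
  ratios of hybrid acquisitions; strongly anisotropic resampling would
  warrant partial-volume weighting.
- The mirrored-disk background assumes approximate left–right symmetry
  of unaffected tissue; midline-crossing lesions are rejected rather
  than measured against an invalid background.
- Metrics assume inputs already in SUV units and 10⁻⁶ mm²/s; no dose or
  weight normalisation is performed (ADC maps in SI units are rescaled
  on read).
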