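# fetadc — biparametric FET-PET/ADC lesion analysis for recurrent glioma

After surgery and radio-/chemotherapy, distinguishing recurrent glioma
from post-treatment related effects (PTRE: pseudoprogression,
radionecrosis) is one of the hard problems of neuro-oncologic imaging —
both look alike on conventional MRI. Hybrid PET/MR imaging offers two
complementary quantitative handles measured in the same session and the
same space: amino-acid (FET) tracer uptake, summarised as the
tumour-to-background ratio (TBR), and water diffusivity from DWI,
summarised as the apparent diffusion coefficient (ADC, reported in
10⁻⁶ mm²/s throughout).

`fetadc` implements the volumetric biparametric analysis of such image
pairs for R users (imaging scientists, nuclear-medicine physicists,
methodologists):

- **Segmentation** — the metabolically most active lesion core is
  delineated on the SUV volume by conservative 80% isocontour
  thresholding (IC80): 26-connected supra-threshold components, a
  prominent-lesion selection rule (uptake, then volume, then distance to
  a reference point), and a local re-threshold so the analysed lesion
  always carries a true isocontour of its own peak.
- **VOI transfer and margin adaptation** — the PET-defined VOI is mapped
  onto the co-registered ADC grid by nearest-neighbour assignment of
  voxel centres and trimmed of CSF/fluid voxels (ADC ≥ 2400) and any
  explicit exclusion mask (e.g. a resection cavity).
- **Quantification** — SUVmax, SUV80mean (mean over the IC80 VOI),
  mirrored contralateral background means on the representative slice
  (the slice of highest mean uptake inside the VOI), and the ratios

  TBRmax = SUVmax / SUV-BG,  TBR80mean = SUV80mean / SUV-BG,
  rADCmean = ADCmean / ADC-BG.

- **Cohort statistics** — pooled-variance t-tests (MD ± SE), empirical
  ROC curves with the AUC as the normalised Mann–Whitney statistic and
  DeLong standard errors, DeLong comparison of correlated curves, Youden
  cutoffs, and the step-wise biparametric classifier: *recurrence if
  TBRmax > 2 or ADCmean > 1254*, together with its OR-rule ROC envelope
  and diagnostic measures.
- **Digital phantoms** — a calibrated synthetic PET/ADC phantom
  generator (brain ellipsoid, CSF spheres, generalized-Gaussian hot
  lesion, correlated PET noise) whose group calibrations reproduce
  published REC/PTRE group summaries, used to validate the pipeline end
  to end.

## Worked example

Simulate a study-sized cohort (32 recurrences, 10 PTRE) with the
packaged calibrations, run the full pipeline on every phantom, and look
at the cohort report:

```r
library(fetadc)

cals <- default_calibrations()
man  <- generate_cohort(cals, n_rec = 32, n_ptre = 10, seed = 2026,
                        out_dir = "demo_cohort")
rep  <- run_cohort(pipeline_config(), man)
print(rep)
```

```
<cohort_report> 42 patients processed, 0 failed
<group_comparison> adc_mean: 1338 (REC) vs 991.1 (PTRE), MD +/- SE, 347 +/- 92.8, p = 0.000576
<group_comparison> radc_mean: 1.743 (REC) vs 1.315 (PTRE), MD +/- SE, 0.4286 +/- 0.123, p = 0.00117
<group_comparison> tbr80_mean: 2.778 (REC) vs 1.853 (PTRE), MD +/- SE, 0.925 +/- 0.321, p = 0.00639
<group_comparison> tbr_max: 3.202 (REC) vs 2.151 (PTRE), MD +/- SE, 1.052 +/- 0.369, p = 0.00695
<roc_result> adc_mean: AUC = 0.822 +/- 0.073 (95% CI 0.633-0.925), p = 1.17e-05  [n = 32/10]
<roc_result> tbr_max: AUC = 0.784 +/- 0.071 (95% CI 0.614-0.893), p = 6.52e-05  [n = 32/10]
<roc_envelope> OR-rule envelope AUC = 0.909 +/- 0.043 (bootstrap 95% CI 0.822-0.984)  [n = 32/10]
  biparametric rule: <classifier_rule> or_rule: TBRmax > 2  OR  ADCmean > 1254
<diagnostic_measures> sens 90.6% / spec 30.0%, PPV 80.6% / NPV 50.0%  (tp 29 fp 7 tn 3 fn 3)
```

The recurrence arm shows higher hot-core ADCmean and TBRmax than the
PTRE arm; each marker alone separates the groups reasonably (AUC ≈ 0.8)
and the two-threshold OR rule dominates both. A single patient is just
as easy:

```r
m <- run_patient(pipeline_config(), man$suv_path[1], man$adc_path[1], "REC_001")
print(m)
classify_biparametric(m)
```

```
<lesion_metrics> REC_001
  SUVmax 1.829  SUV80mean 1.580  SUV-BG 0.920  ->  TBRmax 1.99  TBR80mean 1.72
  ADCmean 884  ADC-BG 762  ->  rADCmean 1.16   (VOI 1100 mm^3)
[1] "PTRE"
```

This phantom drew a low target TBR and a low hot-core ADC, so neither
marker fires — the rule calls it PTRE. A command-line front end with the
same functionality ships at `inst/cli/fetadc.R`
(`simulate` / `cohort` / `classify` subcommands).

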