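Package: fetadc
Title: Biparametric FET-PET/ADC Lesion Analysis for Recurrent Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric biparametric analysis of co-registered amino-acid
    (FET) PET and diffusion (ADC) brain volumes for differentiating
    recurrent glioma from post-treatment related effects. Implements
    80%-isocontour (IC80) hot-spot segmentation with prominent-lesion
    selection, nearest-neighbour VOI transfer between grids, margin
    adaptation against cerebrospinal fluid, mirrored contralateral
    background regions, tumour-to-background and relative-ADC ratio
    quantification, cohort statistics (pooled t-tests, empirical ROC with
    DeLong variance, Youden cutoffs, a step-wise two-threshold classifier
    and its OR-rule ROC envelope), and a calibrated digital PET/ADC
    phantom generator for end-to-end validation on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
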