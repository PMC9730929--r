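Package: petmip
Title: Surrogate Lymphoma Biomarkers from PET Maximum-Intensity Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the 3D prognostic biomarkers total metabolic tumor volume
    (TMTV, cm3) and lesion dissemination (Dmax, cm) from whole-body FDG-PET
    lesion masks, together with their 2D surrogates sTMTV (cm2) and sDmax (cm)
    measured on coronal and sagittal maximum-intensity projections (MIPs).
    Includes a minimal NIfTI-1 reader/writer, a synthetic whole-body PET
    phantom generator with linked simulated survival outcomes, pluggable 2D
    lesion segmenters (a deterministic intensity baseline and a compact
    trainable encoder-decoder with patientwise k-fold cross-validation),
    segmentation agreement statistics (Dice, sensitivity, specificity,
    Wilcoxon, Spearman, median-split concordance, risk-category agreement),
    and survival analysis (Kaplan-Meier, Cox hazard ratios with bootstrap
    confidence intervals, time-dependent AUC, TMTV-by-Dmax three-category
    risk stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
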