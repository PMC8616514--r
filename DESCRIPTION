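Package: wltb
Title: Whole-Liver Tumor Burden Imaging Biomarkers and Survival Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative imaging biomarkers (QIBs) of the whole liver tumor
    burden (WLTB) computed from 3D CT volumes and co-registered segmentations:
    first-order attenuation and volume measures, tumor burden score, bilobar
    disease, geometric metastatic spread along the scanner axes,
    surface-area-to-volume ratio, and the four-feature radiomics signature
    (energy, compactness, gray-level run-length nonuniformity, wavelet
    nonuniformity). Includes a synthetic liver-phantom cohort generator with
    proportional-hazards survival simulation, clinical baseline Cox models for
    metastatic pancreatic cancer, extension of the baselines with imaging
    features via univariable screening and AIC backward elimination, nested
    likelihood-ratio model comparison, concordance indices, and median-split
    risk stratification with Kaplan-Meier curves and log-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
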