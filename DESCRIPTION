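Package: plaquekit
Title: Coronary Plaque Quantification, Co-Registration and Agreement Analysis on Synthetic Vessel Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies coronary atherosclerotic plaque from volumetric
    CT-attenuation images the way contemporary CCTA plaque-analysis tools do:
    per-station cross-sectional lumen/vessel/plaque areas along a centerline,
    Hounsfield-unit plaque characterization with an adaptive calcium
    threshold, and Simpson's-rule volumetrics. Emulates the paired
    intravascular-ultrasound (IVUS) pullback (per-millimetre areas, plaque
    burden, lesion detection under the full-thickness assumption), co-registers
    the two modalities through anchored monotone 1D lumen-profile warping, and
    computes the full agreement battery (Pearson with regression, intraclass
    correlation, Bland-Altman limits, paired t, ROC for low-attenuation-plaque
    presence). A seeded digital vessel-phantom generator with analytic ground
    truth makes every stage verifiable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    RNifti,
    digest
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
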