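Package: gavageNMR
Title: Plasma 1H-NMR Biomarker Discovery for Duck Foie Gras Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for discovering plasma 1H-NMR
    biomarkers of fatty-liver (foie gras) quality traits in overfed mule
    ducks: liver weight (LW) and cooking technological yield (TY). Provides
    a synthetic-cohort and spectrum simulator with planted effects, spectral
    calibration and alignment, fixed-width (0.01 ppm) bucketing with solvent
    exclusions, fingerprint-based metabolite quantification by non-negative
    least squares, relative-concentration scoring from bucket data, Pareto
    scaling, single-component NIPALS partial least squares with VIP scores,
    7-fold cross-validated Q2, RMSEE/RMSECv, permutation-based model
    validation, Benjamini-Hochberg univariate biomarker screening,
    two-method reconciliation (Venn), and biomarker-trait correlation
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
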