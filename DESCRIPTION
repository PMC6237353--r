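Package: MetaboBench
Title: Targeted and Non-Targeted Metabolomics Quantification, Drift
    Correction and Precision Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition computation layer for combined targeted and
    non-targeted metabolomics workflows. Provides internal-standard based
    quantification with weighted calibration curves, isotopic (M+2)
    deconvolution of flow-injection lipid MRM data, QC-anchored signal-drift
    and batch correction with RSD-threshold benchmarking, lipid
    fragment-to-parent matching and putative-identification filtering of
    annotated high-resolution feature tables, and precision/accuracy
    comparison of targeted versus non-targeted platforms. Includes synthetic
    data generators emulating the statistical structure of MRM peak-area
    matrices, isotope-overlapped lipid panels and drifting injection
    sequences, so every stage can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readxl,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
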