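Package: myoquant
Title: Quantitative Pipeline for Dystrophic Muscle Imaging, Elastase
    Kinetics and Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable implementations of the three quantitative stages of a
    dystrophic-muscle elastase study: fluorescence-micrograph quantification
    (Li and Triangle histogram thresholding, distance-transform watershed
    separation of touching nuclei, a 900-pixel size filter, and myogenesis
    indices computed by mask logic), fluorogenic protease-activity kinetics
    (blank subtraction, technical-replicate averaging, inhibitor-sensitive
    fraction extraction and percent inhibition from least-squares rates),
    and label-free LC-MS differential abundance (charge filtering,
    median-log-ratio run normalisation, unique-peptide protein rollup,
    replicate-correlation QC, per-age two-group ANOVA with Bonferroni
    correction). A synthetic-data module generates ground-truthed
    micrographs, plate-reader kinetic series and peptide tables emulating
    the study design, so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
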