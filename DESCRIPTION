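Package: glioLipidIMS
Title: MALDI Imaging Lipidomics of Glioblastoma Proliferative Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for MALDI imaging mass spectrometry (IMS)
    lipidomics of healthy and glioblastoma brain tissue with or without
    temozolomide treatment, together with downstream transcriptome, survival
    and methylation analytics. Provides sum-composition lipid mass arithmetic
    and ppm annotation, a synthetic-data generator that plants
    literature-parameterized lipid compositions and co-expression modules,
    pixel-spectrum alignment and TIC normalization, segmentation with ROI
    matching, class/species composition statistics, co-expression module
    detection with subtype enrichment scores, and Kaplan-Meier/log-rank and
    ANOVA/Tukey comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
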