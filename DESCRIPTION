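Package: grassmet
Title: Untargeted LC-MS Metabotyping of Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mining of large multi-batch untargeted LC-MS peak tables for
    population-level metabolic variation. Provides quality-control filtering
    (duplicate-peak merging, parametric empirical-Bayes batch correction,
    residual-batch F filtering, replicate CV screening with modified Z-score
    outlier removal, invariance filtering, PCA diagnostics), isotope-envelope
    de-isotoping, moderated differential testing across populations with FDR
    control, UPGMA clustering of population profiles, aggregation of isobaric
    peaks split by retention-time misalignment, and rule-based annotation of
    flavonoid glycosides and alkaloids from accurate mass and neutral losses,
    with NIST MSP spectral library input/output. A synthetic-data generator
    emulates a multi-batch clonally replicated population survey with known
    ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
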