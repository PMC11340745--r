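Package: miREO
Title: Reference-Based Relative Expression Ordering Analysis of Blood miRNA
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially expressed miRNAs in mixed-cell whole-blood
    samples that reflect intracellular changes within leukocytes rather than
    shifts in leukocyte proportions. Mines miRNA pairs whose within-sample
    relative expression ordering (REO) is stable across purified leukocyte
    subtypes, detects disease-associated reversals of those orderings with
    Fisher's exact test, and iteratively extracts dysregulated miRNAs from the
    reversal pairs. Includes one-vs-rest derivation of leukocyte-subtype
    miRNA signatures, single-sample gene set enrichment (ssGSEA) scoring of
    composition shifts, cumulative hypergeometric overlap tests, a
    label-permutation null, and a synthetic whole-blood mixture simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    ImmunoOncology, Software
RoxygenNote: 7.3.3
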