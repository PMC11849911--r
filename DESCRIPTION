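Package: dielWL
Title: Diel Transcriptome, Growth and Metabolite Analysis of Water-Limitation
    Responses in Allopolyploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing prolonged water-limitation experiments in
    allopolyploid crops such as Brassica napus. Fits a Bayesian distributional
    Gompertz growth model (Student-t likelihood with a logistic variance
    sub-model) by adaptive Metropolis MCMC and evaluates posterior hypotheses
    on growth parameters; detects water-limitation-responsive genes in diel
    (ZT 1/7/13/19) expression time courses through eigengene-based
    pattern-change (kME) and median-change (Med) scores against a permutation
    null; classifies phase changes into five circular groups and quantifies
    subgenome and homoeolog divergence; builds response-score co-expression
    modules with eigengene summaries; performs hypergeometric term enrichment
    with broad-descriptor rollups; and normalizes and censors targeted
    metabolomics feature tables at detection and quantification limits.
    Includes simulators for growth, expression and metabolite data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    edgeR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
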