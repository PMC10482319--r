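Package: growthCUB
Title: Growth-Rate-Dependent Expression Variation and Codon Usage Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking growth-rate-dependent gene expression variation to
    codon usage bias in microbes. Scores coding sequences with codon usage
    bias metrics (CAI, tAI) as geometric means of codon weights; loads,
    quality-filters, normalizes, replicate-averages and subsets expression
    compendia with growth-rate metadata; computes the per-gene Growth
    Correlation Index (GCI, the Pearson correlation between expression and
    growth rate across conditions) with a permutation null; relates
    per-condition expression-CUB fits to growth rate; compares four linear
    models predicting CUB from mean expression and GCI with adjusted R-squared
    and variance-inflation diagnostics; and tests gene classifications and
    annotation terms for association with GCI via pooled t-tests and
    hypergeometric over-representation with Benjamini-Hochberg correction.
    Includes a synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
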