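Package: daareplic
Title: Replicability Evaluation for Microbial Differential Abundance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the consistency and replicability of
    differential abundance analysis (DAA) methods on microbial count data.
    Provides a seeded generator of compositional, zero-heavy taxa-by-sample
    count datasets with known ground truth; prevalence filtering and
    total-sum-scaling normalization; elementary per-taxon DAA methods
    (proportional-odds ordinal regression, linear regression of
    log-transformed relative abundances, presence/absence logistic
    regression, and a negative binomial count model) with
    Benjamini-Hochberg false discovery rate control; and split-data and
    separate-study replication protocols with their consistency and
    sensitivity metrics: percentages of conflicting and replicated
    candidate taxa, number of hits, pooled Spearman correlation of effect
    estimates, and the overlap percentage of confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
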