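Package: dnmrisk
Title: De Novo Mutation Burden and Risk-Gene Discovery in Parent-Child Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trio-based de novo mutation (DNM) analysis for rare disease
    cohorts: quality-control filtering of candidate DNM calls (identity-by-
    descent checks, region masks, genotype-quality/strand-bias/depth filters
    and Mendelian criteria with a per-rule audit trail), class-wise burden
    testing against a per-gene mutation-rate null model with exact Poisson
    statistics, permutation-based maximum-likelihood estimation of the number
    of risk genes from recurrent damaging DNMs, de novo-only TADA Bayes
    factors with sampling-based p-values and Bayesian FDR q-values, and
    cross-cohort enrichment tests (Poisson tails and Fisher's exact test).
    A seeded synthetic-cohort generator emulates the statistical structure the
    analysis assumes so that every stage runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
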