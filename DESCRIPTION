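Package: sarcosig
Title: Gene-Signature Scoring and Subtype Stratification for Sarcoma
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("sarcosig", "developers", email = "sarcosig@example.org",
           role = c("aut", "cre"))
Description: Tools to score bulk expression cohorts with directional gene
    signatures (signed algebraic sums of log-scale expression), stratify
    samples by top-fraction score, test subtype enrichment and set overlap
    with the hypergeometric distribution, cluster samples on signature
    genes, and build signatures by cross-species homolog mapping, signature
    overlap, and differential expression. Includes auxiliary quantifications
    used alongside such analyses (qPCR standard-curve relative copy number,
    FISH per-cell signal summaries, z-scores against a normal-tissue panel)
    and a synthetic-data module that simulates expression cohorts, qPCR
    plates and FISH cell tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
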