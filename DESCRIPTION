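Package: streamscape
Title: Riverscape Population Genomics for Assisted-Migration Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rangewide riverscape genomic assessment of fishes in
    dendritic stream networks: pairwise FST and expected heterozygosity with
    bootstrap confidence intervals, river-network distances and path-level
    habitat covariates, isolation-by-distance landscape models with
    exhaustive AIC model selection and within-metapopulation permutation
    inference, linkage-disequilibrium effective population size estimation
    with sample-size bias correction and jackknife confidence intervals,
    runs-of-homozygosity detection, genetic-load and structural-variant
    summaries, and a transparent donor/recipient scoring framework for
    prioritizing populations for assisted gene flow. Includes a synthetic
    river-network genotype simulator so every stage of the pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
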