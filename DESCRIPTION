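Package: adsig
Title: Longitudinal Transcriptome-Phenotype Association Analysis for
    Alzheimer's Mouse Cohorts
Version: 0.1.0
Authors@R:
    person("adsig", "maintainers", email = "adsig@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal bulk RNA-seq cohorts profiled together
    with behavioral and biochemical phenotypes, modeled on two-genotype
    (wild-type vs transgenic) mouse designs sampled at several ages.
    Implements gene filtering on RPKM, trimmed-mean-of-M-values (TMM)
    normalization, classical MDS ordination, per-age negative-binomial
    exact-test differential expression with Benjamini-Hochberg correction,
    pooling of directional DEG sets, pairwise DEG-overlap chi-square tests,
    a competitive randomization test linking gene-set expression to
    per-animal phenotypes via mean absolute Pearson correlation against
    equally sized random background sets, and hypergeometric
    over-representation analysis against GMT annotations. A seeded
    synthetic-cohort generator with full ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
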