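Package: gbmnet
Title: Integrated Mutation, mRNA and miRNA Network Analysis for Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated network analysis of tumor multi-omic data:
    a Poisson-based group burden test of somatic and loss-of-heterozygosity
    mutations (genotype and allele-count variants), Wilcoxon differential
    expression with Bonferroni control, joint symmetric lasso estimation of
    Gaussian graphical coexpression networks by coordinate descent, module
    detection with Fisher exact pathway enrichment, damage-value node
    ranking for network robustness, regression-based filtering of candidate
    miRNA-target pairs, group-regression cis/trans eQTL mapping with
    triangle regulation cycle detection, and univariate Cox screening of
    expression signatures against survival. A synthetic-data generator
    reproduces the statistical structure the analyses assume, so the whole
    pipeline runs and is testable without access to protected tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
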