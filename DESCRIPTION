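Package: sumtwas
Title: Transcriptome-Wide Association Studies from Summary-Level eQTL Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains per-gene expression prediction models directly from
    summary-level cis-eQTL statistics (z-scores and per-SNP sample sizes) by
    coordinate-descent penalized regression (LASSO, elastic net, MCP, SCAD,
    MNet) against a genetic-distance shrinkage estimator of the linkage
    disequilibrium matrix, tunes and validates the models on individual-level
    expression panels, tests gene-trait associations against GWAS summary
    statistics with a burden-type z-statistic, and aggregates the per-penalty
    p-values with an R-squared-weighted Cauchy combination test. Includes a
    simulation framework (LD-structured genotypes, expression and phenotype
    generation, derived summary statistics) for accuracy, power and type-I
    error experiments, readers and writers for PLINK bed/bim/fam panels,
    tab-delimited eQTL/GWAS summary files and genetic maps, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    vcfR
Config/testthat/edition: 3
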