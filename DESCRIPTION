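Package: branchomega
Title: Branch-Wise dN/dS Estimation and Lineage Constraint Contrasts for Gene Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for disease-gene sets on a
    mammalian species tree. Builds in-frame codon alignments from protein
    alignments, estimates per-branch dN/dS under a Goldman-Yang codon
    substitution model (single-ratio, foreground/background branch models and
    free-ratio) by maximum likelihood with Felsenstein pruning, cross-checks
    estimates with the Nei-Gojobori counting method, screens putative orthologs
    whose synonymous divergence from a reference species is an extreme outlier,
    summarises gene classes per lineage with the ratio-of-means dN/dS
    convention, and contrasts lineages with all-pairs one-way ANOVA under
    Bonferroni correction. Includes a branch-specific-omega codon sequence
    simulator so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
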