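Package: fasterX
Title: Faster-X Analysis of Gene Expression and Protein-Coding Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing faster-X evolution of gene expression and
    protein-coding sequences between closely related Drosophila species.
    Implements the tau tissue-specificity index, pairwise maximum-likelihood
    dN/dS estimation under a single-ratio codon substitution model with F3x4
    equilibrium frequencies, Nei-Gojobori (1986) counting with Jukes-Cantor
    correction, consensus-site and gene-level quality filters, standardized
    multiple-regression residual contrasts, and a decile-stratified matched
    X-versus-autosome Wilcoxon comparison, together with a synthetic-data
    generator (codon-sequence simulation under the same model, correlated
    gene-property covariates, configuration-model interaction networks) for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
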