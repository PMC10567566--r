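Package: perturbscope
Title: Transcriptional Linkage Analysis for In Vivo Pooled CRISPR Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Perturbscope", "Developers", email = "maintainer@perturbscope.dev",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-nucleus pooled CRISPR perturbation
    screens and deletion-model cohorts: guide RNA assignment from per-nucleus
    capture tables, pseudobulk negative-binomial GLM likelihood-ratio
    differential expression, linear-discriminant filtering of non-perturbed
    (mosaic) nuclei, Hotelling T-squared perturbation scoring, perturbation
    gene programs and program scores, robust-regression decomposition of an
    aggregate deletion phenotype into single-gene perturbation signatures via
    Huber M-estimation and distance correlation, and diffusion-map dissection
    of zygosity states. Includes a synthetic-data generator with known ground
    truth so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    methods,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    edgeR
Config/testthat/edition: 3
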