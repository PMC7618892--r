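Package: denovoms
Title: De Novo Peptide Sequencing from Tandem Mass Spectra with
    Mass-Constrained Decoding and Diffusion Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for transformer-based de novo peptide
    sequencing from tandem mass spectra. Implements multi-scale sinusoidal
    peak encoding, an autoregressive transformer decoder trained with
    cross-entropy, knapsack-filtered beam search that constrains decoded
    peptides to the precursor mass within a ppm tolerance, a multinomial
    diffusion model that iteratively refines predictions over a discrete
    noise schedule, peptide/amino-acid precision-recall evaluation with a
    surrogate FDR confidence threshold, and a synthetic HCD-style spectrum
    simulator so the full pipeline trains and validates without external
    data. Spectra, peptide-spectrum matches and predictions are tibbles;
    models ship with broom-style tidy() and glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
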