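Package: omisurv
Title: Adaptive Microbiome Community-Level Association Tests for Survival
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variance-component score tests that relate microbial community
    composition to censored survival outcomes under a Cox proportional
    hazards null model.  Implements MiSALN (powered-abundance correlation
    structures), kernel machine tests over ecological distances (unweighted,
    generalized and weighted UniFrac, Bray-Curtis), and the adaptive minimum
    p-value combinations OMiSALN, OMiRKAT-S and OMiSA, with p-values from a
    shared residual-permutation ensemble.  Includes a hierarchical taxon
    scan across taxonomic ranks with Benjamini-Hochberg correction, and a
    Dirichlet-multinomial simulation harness for type I error and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    biomformat,
    cluster,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
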