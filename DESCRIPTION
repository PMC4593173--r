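Package: ssvepflow
Title: Model- and Data-Driven Directed Connectivity Analysis for SSVEP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing directed information flow between
    visual cortex and frontal area during steady-state visual evoked
    potential (SSVEP) experiments. Provides a coupled double-column
    Jansen-Rit neural mass model with particle swarm optimization (PSO)
    inversion to estimate intra-column (C1, C2) and inter-column (K1, K2)
    coupling from two-channel recordings, a partial directed coherence
    (PDC) pipeline over a multivariate autoregressive fit with AIC order
    selection and band-averaged flow aggregation between electrode groups,
    repeated-measures ANOVA with Greenhouse-Geisser correction and
    Bonferroni-corrected paired t post-hoc tests, and a synthetic-data
    generator emulating a multi-subject, multi-condition study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
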