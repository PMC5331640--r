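Package: microvar
Title: Intra-Patient Temporal Variability of Longitudinal Microbiomes
Version: 0.1.0
Authors@R:
    person("microvar", "developers", email = "microvar@example.org",
           role = c("aut", "cre"))
Description: Quantifies intra-patient temporal variability of oral and gut
    microbial communities sampled longitudinally, as the coefficient of
    variation (CV) of per-sample alpha-diversity (Shannon, Simpson, Chao-1)
    and of within-patient UniFrac distances (unweighted and weighted).
    Classifies patients per body site into stable / average / variable
    categories by cohort CV quartiles, and screens for associations between
    variability and genus-level relative abundances (Pearson correlation,
    Kruskal-Wallis across stability categories with Benjamini-Hochberg
    correction), clinical outcomes (Welch t, Mann-Whitney U), and clinical
    covariates (multivariable ordinary least squares). Includes a seeded
    synthetic longitudinal-cohort generator with planted per-patient
    volatility, pathogen-bloom dynamics, and antibiotic-exposure coupling,
    so that the full pipeline is testable with known ground truth, plus
    readers and writers for tab-separated feature tables, metadata and
    distance matrices and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phyloseq,
    withr
Config/testthat/edition: 3
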