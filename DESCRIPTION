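Package: convflight
Title: Convergent Substitution Scanning and Metabolic Fuel-Switch
    Modelling for Flight-Degenerate Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting convergent molecular evolution between a
    foreground phenotype group (flight-degenerate birds) and a background
    group (flying birds) from multiple sequence alignments and a phylogeny:
    a per-site two-group frequency scan with Fisher's exact test, a
    neutral-expectation convergent-substitution test based on Felsenstein
    pruning with discrete-gamma rate heterogeneity, marginal ancestral
    reconstruction of focal codons with a genotype-to-flight-phenotype map,
    and a kinetic model of antagonistic lipid/carbohydrate metabolism that
    predicts the dominant muscle fuel as lipase and thioesterase activities
    change. A synthetic-data module simulates alignments along a tree under
    a reversible substitution model and plants convergent substitutions so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
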