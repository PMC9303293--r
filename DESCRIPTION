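Package: g4invader
Title: Design and Quantitative Analysis of LNA Invader Probes that
    Disrupt DNA G-Quadruplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the rational design of locked nucleic acid (LNA)
    modified oligonucleotide probes that invade and disrupt DNA
    G-quadruplexes (G4), and for the quantitative assays used to
    characterise them. Includes G-tract/loop annotation of G4-forming
    sequences and rule-based placement of LNA modifications; one-phase
    exponential fitting of bulk FRET disruption kinetics with biphasic
    (slow-phase) handling and summary-statistic t tests; UV-melting Tm
    extraction; single-molecule force-spectroscopy analysis converting
    stretch/relax hysteresis into contour-length-change profiles, folded-G4
    counts (9 nm per unit) and the half-disruption force F1/2; polymerase
    stop-assay quantification of full-length versus stalled products; and
    the dual-luciferase reporter pipeline (max-normalisation, Shapiro-Wilk,
    one-way ANOVA, Dunnett many-to-one comparisons). Seeded synthetic-data
    generators emulate every input modality so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
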