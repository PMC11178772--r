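Package: fibrintools
Title: In Silico Fibrinolysis: Protease Specificity Scanning, Structural
    Metrics, and Clot-Lysis Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the fibrinolytic action of cysteine
    proteases such as kiwifruit actinidin. Implements a positional
    (Schechter-Berger P4-P4') substrate-specificity model and cleavage-site
    scanner for fibrin chains, a docking-peptide window builder,
    first-principles structural metrics (Kabsch superposition RMSD,
    backbone torsions with Ramachandran classification, Shrake-Rupley
    solvent-accessible surface area, atom-pair distances), catalytic-pose
    screening and trajectory summaries (hydrogen-bond counts, SG-C
    distance series and box-plot statistics), Gibbs free energy to
    dissociation constant conversion, clot-lysis degradation percentages
    with one-way ANOVA and Bonferroni/Holm post-hoc tests, and seeded
    synthetic-data generators so every stage can be exercised without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
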