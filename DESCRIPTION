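Package: pnimut
Title: Binding Affinity Changes of Missense Mutations in Protein-Nucleic-Acid Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding free energy changes (ddG) caused by missense
    mutations in protein-DNA and protein-RNA complexes. Computes geometric
    partition-based energy features from per-residue-pair energy
    decompositions, interface-based structural features (solvent
    accessibility, hydrogen bonds, contacts, conservation), performs
    group-wise sequential backward feature selection, and combines energy-
    and nonenergy-based random-forest models into a weighted ensemble for
    both regression (ddG) and classification of affinity-decreasing
    mutations, evaluated by leave-one-complex-out cross-validation. Includes
    a synthetic-fixture generator producing toy complexes, planted-signal
    energy tables, conservation profiles and full mutation datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
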