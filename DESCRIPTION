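Package: heterotic
Title: Heterotic Grouping and Line x Tester Analysis for Hybrid Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies heterotic groups in a germplasm panel by integrating
    continuous agro-morphological traits with binary SSR-marker and seed-protein
    band profiles, scaling all features to [0,1] (optionally after a Yeo-Johnson
    power transform) and clustering with from-scratch Ward.D2 agglomeration,
    Lloyd k-means (k-means++ initialization) and a hybrid
    hierarchical-then-k-means algorithm. Evaluates the resulting groups through
    a Line x Tester mating design: mid-parent and better-parent heterosis with
    t-based significance, general and specific combining ability with a
    randomized-block ANOVA, and standard errors for all effect classes. Ships a
    synthetic germplasm-panel and trial generator with known ground truth, and
    an embedded fixture of published sunflower parent and hybrid trait means
    for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
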