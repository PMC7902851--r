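Package: jawmorph
Title: Jaw-Shape Morphospace, Mechanical Advantage and Phylogenetic
    Discriminant Analysis of Mammalian Diets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diet-focused ecomorphology of mammalian lower jaws:
    generalized Procrustes analysis of 2D landmark configurations with
    iterative sliding of semi-landmarks, principal-component morphospaces
    with out-of-sample projection of fossil shapes, masseter and temporalis
    mechanical advantage from moment-arm lengths, permutation tests of
    diet-group separation (Procrustes ANOVA with residual randomization,
    optionally phylogenetically transformed, and one-way PERMANOVA), and
    phylogenetic flexible discriminant analysis with Pagel's lambda that
    assigns dietary posterior probabilities to fossil taxa. Also provides
    time-scaling of cladograms from first-appearance dates (the "equal"
    method), TPS landmark-file input/output, and a ground-truthed
    synthetic-data generator used throughout the test suite.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
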