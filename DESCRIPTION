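Package: cann
Title: Cerebellar Circuit Models of Next-Word Prediction and Emergent Syntax
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a biologically constrained cerebellar circuit
    (granule-cell input layer, Purkinje middle layer, nucleus output layer,
    plus the nucleocortical recurrent pathway) trained for next-word
    prediction with climbing-fiber prediction-error learning. Provides
    sign-constrained and modular ("convergent") circuit variants, a labelled
    synthetic subject-verb-object grammar for reproducible experiments, and a
    representation-probing toolkit: top-k prediction scoring, PCA activity
    trajectories, repeated-split support-vector-machine separability of
    syntactic roles, linear separating directions, and synaptic weight
    distribution statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
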