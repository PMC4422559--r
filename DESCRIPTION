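Package: hubmotif
Title: Probabilistic Assignment of Metabolites to Causal Network Motifs
    Around a Signaling Hub
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the causal position of metabolites relative to a
    signaling hub (such as yeast TORC1) from dynamic metabolite and
    transcript time courses measured under nutrient-shift and
    drug-bypass perturbations.  For every metabolite it computes a
    delayed distance-correlation "dynamic dependence" feature against
    the rate of change of every transcript, a "representation of hub
    genes" feature from a transcription-factor target prior, and uses
    Bayes factors with empirical-CDF likelihoods against a
    random-metabolite null ensemble to assign each metabolite to one of
    four network motifs (upstream, downstream, parallel, unrelated) by
    majority vote over 48 method variants.  Includes robustness
    analysis under perturbations of the hub transcription-factor prior,
    a six-parameter impulse-model fit of transcriptional onset times,
    and a synthetic-data generator with planted motif structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
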