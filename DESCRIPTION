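Package: seizescreen
Title: Electrographic and Behavioral Seizure Phenotyping for Larval Zebrafish Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale epilepsy phenotyping of larval zebrafish
    mutant lines. Implements threshold-binarization / sliding-window raster
    scoring to detect electrographic events in local field potential (LFP)
    recordings, classifies events into interictal-like (type I) and ictal-like
    (type II) classes, scores recordings on the 0/1/2 LFP scale and aggregates
    per-line epilepsy calls; segments swim trajectories into movement bouts and
    flags convulsive seizure-like events; provides Kaplan-Meier survival and
    log-rank cohort statistics and a gene-orthology homology score. A synthetic
    data module generates LFP traces, swim tracks and survival cohorts with
    ground-truth annotations so the whole pipeline is testable without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    signal,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'behavior.R'
    'detect.R'
    'io.R'
    'scoring.R'
    'screen.R'
    'seizescreen-package.R'
    'stats.R'
    'synth-lfp.R'
    'synth-survival.R'
    'synth-track.R'
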