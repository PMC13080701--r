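Package: hepline
Title: Heartbeat-Evoked Potential Analysis of Peri-Ictal EEG/ECG Polygraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: R-wave-locked back-averaging of scalp EEG to derive the
    heartbeat evoked potential (HEP) around seizures and around symptom
    reports during tilt-table testing. Implements EDF+ reading and writing,
    band-pass filtering and artifact subspace reconstruction, R-peak
    detection and heart-rate-variability metrics, epoch extraction with
    R-R-interval and peak-to-peak amplitude rejection rules, compound-lead
    HEP amplitudes, peri-event segmentation for the seizure and tilt-table
    study arms, and subject-level bootstrapped inference with empirical
    p-values.  A synthetic polygraphy generator with known ground-truth
    effects provides parameter-recovery oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
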