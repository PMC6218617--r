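Package: mures
Title: Mu-Rhythm Desynchronization, Multiscale Entropy and Phase-Coherence
    Networks for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for studying motor resonance in
    multichannel EEG: event-related desynchronization of the mu rhythm
    (8-13 Hz) from Welch band power, multiscale (sample) entropy of raw and
    band-limited signals, phase-locking-value connectivity networks with
    weighted clustering coefficient and global efficiency, and the
    group-level statistics that link baseline signal complexity to
    desynchronization. Includes a synthetic EEG generator with known band
    powers, known task-versus-rest alpha suppression and known pairwise
    phase coupling, so that every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
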