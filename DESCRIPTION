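Package: epinetdyn
Title: Dynamic Phase-Locking Networks and Link Prediction for Seizure Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms multichannel intracranial EEG into time-varying,
    frequency-specific phase-locking-value (PLV) networks, ranks node pairs
    with common-neighbour link-prediction similarity indices (common
    neighbours, resource allocation, Adamic-Adar, Sorenson), benchmarks the
    indices by sampled AUC under randomized train/probe edge splits, and
    tracks seizure initiation and termination through node-sequence
    variation (cosine similarity, Euclidean distance) and node index
    summation separating intrafocus from extrafocus recording sites.
    Includes a coupled phase-oscillator EEG simulator with a controllable
    hypersynchronous ictal epoch and seeded random-graph generators for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
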