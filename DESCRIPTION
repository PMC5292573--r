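Package: fcnet
Title: Functional Connectivity Indices and Weighted Network Metrics for
    Neurophysiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimation of functional connectivity between multichannel
    neurophysiological time series (EEG/MEG-like) and graph-theoretical
    analysis of the resulting weighted networks.  Implements zero-phase
    FIR filtering executed in the frequency domain, Hilbert-phase
    synchronization indices (phase locking value, phase lag index,
    imaginary part of coherency, weighted phase lag index) with a
    Rayleigh-test significance approximation and false-discovery-rate
    correction, Kraskov k-nearest-neighbour mutual information with
    marginal entropies and two normalizations, generalized
    synchronization indices (S, H, M, L) from delay embeddings, and
    weighted network measures (strength, clustering coefficient,
    shortest path length, betweenness centrality).  Seeded generators of
    coupled oscillators, unidirectionally coupled Henon maps and random
    weighted graphs provide ground-truth test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
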