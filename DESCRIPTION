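Package: megstates
Title: Disentangling Transient Brain States from Resting-State MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments resting-state MEG (or EEG) sensor recordings into
    transient spatiotemporal brain states with a time-delay embedded,
    ICA-reduced hidden Markov model fitted by variational Bayes, localizes
    each state's generator with an LCMV beamformer, builds per-state
    directed connectivity networks with partial directed coherence on
    68-region cortical time courses, and scores states for pathological
    (epileptogenic) character with a graph feature index combining the
    weighted clustering coefficient and the hemispheric betweenness
    centrality difference.  Includes a Monte-Carlo simulator of oscillatory
    cortical states through a single-sphere magnetometer forward model for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
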