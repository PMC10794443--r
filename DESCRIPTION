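Package: spikeTopo
Title: Topological Analysis of Criticality in Stochastic Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a fully connected excitatory/inhibitory network of
    stochastic leaky integrate-and-fire neurons with a mean-field
    directed-percolation critical point controlled by the inhibition ratio,
    extracts neuronal avalanches and pairwise spike-train dissimilarities
    (binned Pearson correlation, SPIKE-synchronization, SPIKE-distance),
    computes Vietoris-Rips persistent homology and Betti-curve features of
    the resulting weighted graphs, and classifies sub-critical, critical and
    super-critical dynamical regimes with a radial-basis-function support
    vector machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
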