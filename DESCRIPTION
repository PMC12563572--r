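Package: gnmea
Title: Generative Network Models for Microelectrode-Array Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the self-organisation of developing in-vitro
    neuronal networks recorded on high-density microelectrode arrays.
    Functional connectivity is inferred from spike trains with the spike time
    tiling coefficient (STTC) and jittered-surrogate significance testing;
    thirteen economic generative wiring rules (spatial, homophily, clustering
    and degree based) are fitted by Voronoi-tessellation search over the two
    wiring parameters; model fits are scored with the energy (maximum
    Kolmogorov-Smirnov distance over nodal statistics) and topological
    fingerprint dissimilarity objectives. A seeded synthetic spike-train
    generator emulating developing cultures makes the whole pipeline testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
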