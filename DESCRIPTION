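Package: loopshape
Title: Geometry-Based Selection and Flexibility Classification of Protein Loop Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ensembles of protein loop conformers.
    Computes nine geometric shape descriptors of a loop (anchor, reference
    and pairwise C-alpha distances, consecutive backbone separation,
    loop-to-protein contact distance and a convex-hull volume-to-area
    sphericity proxy), selects diverse representative models from large
    conformer ensembles by PCA and K-means clustering with per-cluster
    medoids, classifies loops as static or flexible from the relative
    standard deviation of arch-shape descriptors, and assigns trajectory
    frames to open/semi-open/closed conformational states with occupancy
    and transition statistics. Includes multi-model PDB input/output and a
    synthetic loop-ensemble generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
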