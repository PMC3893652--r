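Package: swarmdim
Title: Manifold Dimensionality of Collective Animal Behaviour from Raw Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collective behaviour in animal groups directly from
    video, without tracking individuals. Frame stacks are treated as points
    in pixel space and embedded with ISOMAP (nu-nearest-neighbour graph,
    graph geodesics, classical multidimensional scaling); the dimensionality
    of the embedding manifold, read off the residual-variance curve, serves
    as an objective collective-behaviour measure comparable to human
    observer scores. Includes a self-propelled-particle swarm simulator and
    grey-scale frame renderer to generate fully synthetic studies, speed-
    scaled temporal sampling of video, and the accompanying statistics:
    reliable-trial selection, correlation tests, two-way and one-way ANOVA
    with Fisher's protected LSD post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    tiff,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
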