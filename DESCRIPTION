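Package: dropScreen
Title: Simulation, Signal Processing and Statistics for
    Fluorescence-Activated Droplet Sorting of Filamentous Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational core of a droplet-microfluidic screening
    platform for filamentous fungi: a seeded synthetic droplet-train and
    spectrometer-stream simulator (Poisson single-spore encapsulation,
    fluorogenic substrate turnover during multi-day in-droplet
    incubation, media-dependent hyphal exit), the real-time spectral
    processing chain (background subtraction, Butterworth denoising,
    topographic peak detection, event segmentation, gating), an
    autonomous sort controller with travel-time pulse scheduling, a
    stochastic outcome model of the electrostatic Y-junction sorter with
    its three failure modes, and the screening statistics (binomial GLM
    characterization with inflection points, confusion metrics, Poisson
    occupancy, enzymatic activity and fold change, Brown-Forsythe
    variance comparison, exact binomial confidence bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'chain.R'
    'controller.R'
    'io-formats.R'
    'screen-stats.R'
    'sigproc.R'
    'sorter-physics.R'
    'stream-sim.R'
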