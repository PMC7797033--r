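Package: curtainr
Title: Single-Molecule ssDNA Curtain Translocase Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis of single-molecule ssDNA
    curtain experiments on motor proteins that translocate along
    protein-coated single-stranded DNA. Provides a synthetic-data generator
    (two-channel kymographs with ground truth, photobleaching traces,
    recombinase exchange curves, biolayer interferometry sensorgrams,
    heteroduplex collision movies), kymograph tracking (clearing/exchange
    front detection, punctum centroid tracking, translocation segmentation),
    kinetic fitting (binned Gaussian velocity distributions, exponential
    survival processivity with bootstrap confidence intervals, exponential
    exchange rates, recombinase monomer accounting), photobleaching step
    counting, sensorgram phase analysis with biphasic dissociation fits, and
    kinematic classification of motor encounters with heteroduplex DNA
    joints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
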