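Package: coflowr
Title: Blood Rheology from Co-Flowing-Stream Microfluidic Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies blood viscosity, viscoelasticity and red blood cell
    (RBC) aggregation from co-flowing-stream microfluidic experiments in
    which a test fluid (blood) and a reference fluid share one channel and
    the interface position encodes their viscosity ratio. Implements the
    lumped fluidic-circuit model of the two-stream system (nonlinear and
    linearized forms), exponential time-constant estimation after pump
    on/off transitions, interface and intensity extraction from grayscale
    image stacks via Otsu thresholding, the RBC aggregation index, Maxwell
    viscoelasticity, shear-rate and power-law summaries, a protocol-locked
    synthetic-data generator with ground truth, and a per-period analysis
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
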