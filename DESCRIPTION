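Package: organoidval
Title: Generation and Validation of Synthetic Bright-Field Brain Organoid Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for augmenting small bright-field brain-organoid image
    datasets with an adversarial autoencoder under six alternative
    discriminator losses, and for validating the synthetic images three
    ways: a seven-metric similarity and quality suite with group-level
    aggregation, a psychovisual (expert real-versus-generated decision)
    analysis pipeline with error rates, decision-time statistics and vote
    histograms, and a Kullback-Leibler concordance search over all metric
    combinations. A segmentation-evaluation stage builds training sets
    thresholded by expert votes and scores predicted masks (Dice, F1 and
    related ratios) under leave-one-out. Synthetic organoid images with
    ground-truth masks and simulated expert decision records make every
    stage reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    png,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
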