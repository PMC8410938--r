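Package: widevolt
Title: Widefield Ratiometric FRET-GEVI Voltage Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-camera widefield voltage imaging with
    FRET-based genetically encoded voltage indicators (e.g. VSFP Butterfly 1.2)
    in head-fixed mice. Converts raw donor/acceptor image sequences into
    per-pixel percent dR/R voltage signals (spatial binning, dark-offset
    subtraction, pre-stimulus normalisation, FFT-based heartbeat equalisation,
    ratiometric conversion), registers cortical atlas regions to the imaging
    window via bregma and the midline, extracts region-averaged voltage
    traces, quantifies sensory-evoked responses (peak depolarisation with a
    2-SD inclusion rule, hyperpolarisation, time-to-peak, 50 percent decay,
    paired-pulse adaptation ratios, cylinder-test asymmetry index), classifies
    trials as quiet or movement from a behaviour camera, and produces
    trial-averaged bregma-aligned voltage maps. Includes a forward-model
    synthetic data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    scales,
    tiff,
    yaml,
    jsonlite,
    readr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
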