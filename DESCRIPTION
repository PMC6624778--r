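Package: p300hist
Title: P300 Speller Decoding from Gradient-Orientation Histograms of Signal Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the P300 event-related potential and decodes 6x6
    speller-matrix letters by treating averaged EEG epochs the way an
    electroencephalographer does: each averaged channel signal is drawn as a
    binary plot image, summarised by a SIFT-style 128-bin histogram of pixel
    gradient orientations, and matched to calibration templates with an
    adapted k-Naive-Bayes-Nearest-Neighbor rule. Includes the full
    preprocessing chain (notch, lowpass, FIR decimation, amplitude-based
    artifact rejection, epoch segmentation, ensemble averaging), a synthetic
    oddball-session simulator with known ground truth, offline evaluation of
    character recognition rates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
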