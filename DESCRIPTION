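Package: tsburst
Title: Transcription-Site Quantification and Burst Analysis for Live-Cell
    mRNA Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nascent-transcription dynamics from multi-channel,
    multi-Z fluorescence time lapses of budding yeast carrying phage
    coat-protein (PP7/MS2) stem-loop mRNA reporters. Implements the
    transcription-site statistics HiPix (mean of the k brightest pixels in an
    expanded nucleus minus the whole-cell median) and ConnectedHiPix (the
    morphological-opening/largest-cluster detection variant), per-cell trace
    features (Start/End times, transcription period, maximum, integral,
    responder class), MAPK nuclear-relocation features with censoring, a
    four-rule transcriptional burst (peak) detector, and population-level
    summaries (start-time CDFs, end-time survival, responder fractions,
    quartile analyses). A stochastic simulator of MAPK-gated stress-promoter
    transcription (PolII convoys, osmolyte step/pulse/ramp regimes) renders
    synthetic movies with per-cell ground truth so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
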