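Package: ppg2ecg
Title: Reconstruction of Missing ECG Segments from Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for reconstructing missing electrocardiogram (ECG) segments
    from a simultaneously recorded photoplethysmogram (PPG). Implements the
    full pipeline: paired-record input (CSV, optional WFDB), a synthetic
    generator of paired ECG/PPG records with known beat times, zero-phase
    Chebyshev type-II band-pass filtering, Pan-Tompkins QRS detection,
    block-based systolic peak detection, pulse-arrival-time alignment,
    segmentation into 3-second windows, injection of contiguous missing-ECG
    gaps, dual-U-Net ("WNet") and WNet-BiLSTM one-dimensional encoder-decoder
    reconstruction networks with an Adam trainer, stitching of reconstructed
    segments with cross-correlation realignment, and an evaluation suite
    (Pearson correlation, root mean square error, percentage root mean square
    difference, discrete Frechet distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
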