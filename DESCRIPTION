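Package: lamcsd
Title: Laminar Current-Source Density, Spectral, and Granger-Causality
    Analysis of Cortical Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-trial laminar local field potential
    recordings from cortical multielectrode penetrations. Estimates one
    dimensional current-source density (CSD) profiles by the second spatial
    derivative with Hamming-window spatial smoothing and linear boundary
    extrapolation, computes columnar current-flow measures (averaged
    rectified CSD and the relative residual CSD), layer root-mean-square
    amplitudes, onset latencies, and an electrode-stability
    cross-correlogram. Provides frequency-tuning analysis (response
    detection, best frequency, octave binning, Q40dB bandwidth, layer
    symmetry index), spontaneous columnar event detection, multitaper
    spectral estimation with Benjamini-Hochberg corrected per-bin
    statistics, and time-domain pairwise-conditional Granger causality
    between layer traces via multi-trial vector autoregression. A synthetic
    laminar-recording generator with known ground truth (layer gains,
    latencies, tuning, event rates, oscillations, directed VAR coupling)
    exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
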