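Package: meaburst
Title: Spike Detection, Waveform Clustering and Network Burst Analysis for
    High-Density Microelectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-density microelectrode array (HD-MEA)
    recordings of cultured neuronal networks under optical stimulation.
    Converts raw multi-channel extracellular traces into spike trains
    (zero-phase bandpass filtering, robust MAD-based thresholding, refractory
    deduplication, stimulation-artifact exclusion), groups spikes into
    putative single neurons via multi-electrode waveform extraction, UMAP
    embedding and density clustering, detects network bursts and attributes
    each to its initiating waveform cluster, and computes per-period firing
    rate, presence, synchrony and burst statistics together with
    nonparametric comparisons. Includes a synthetic HD-MEA session generator
    with full ground truth, a point-based marker colocalization counter, and
    an end-to-end orchestrator with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    rhdf5,
    signal,
    stats,
    tools,
    utils,
    uwot
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
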