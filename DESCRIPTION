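Package: hdmea
Title: Spontaneous and Evoked Activity Analysis for High-Density CMOS
    Multielectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of in vitro
    neuronal networks on high-density (64x64) CMOS multielectrode arrays:
    threshold-based spike detection with robust noise estimation, burst and
    network-wide activity metrics, lognormal firing-rate distribution
    fitting, evoked-response analysis around multi-site electrical
    stimulation (artifact removal, post-stimulus time histograms,
    fast/long-lasting response classification, first-spike latencies and
    latency versus distance in circular electrode rings), spike-waveform
    phase categorization with unit isolation, and granulometric
    quantification of synaptic puncta in fluorescence micrographs. Includes
    a synthetic-data module that generates recordings, stimulation
    experiments and puncta images with known ground truth so every stage of
    the pipeline is testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png
Config/testthat/edition: 3
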