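Package: optophys
Title: Analysis of Optically Stimulated Neuronal Activity from Calcium
    Imaging and Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipelines for analysing light-evoked activity in neuronal
    cultures and brain organoids interfaced with photoactive substrates.
    Covers calcium-imaging network-connectivity analysis (truncated-SVD
    movie denoising, Hilbert-phase spike detection, stimulus-evoked
    activation-time maps, Spearman connectivity matrices, Gaussian-mixture
    decomposition of activation-time histograms), microelectrode-array
    metrics (band-pass filtering, adaptive-threshold spike detection,
    burst and network-burst detection, spike-time tiling coefficient,
    cross-correlogram synchrony, Lempel-Ziv complexity, stimulation lag
    times, firing-rate fold changes, PCA/k-means spike sorting with the
    gap statistic), a closed-loop trigger rule translating evoked
    population firing into robot avoidance commands, and pipette-resistance
    Arrhenius thermometry. A synthetic-data module generates
    ground-truthed calcium movies and multichannel recordings so every
    stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mclust,
    cluster,
    igraph,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
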