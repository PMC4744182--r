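Package: cortiphys
Title: Quantification of Cortical Neuron Electrophysiology, Morphometry,
    and Laminar Composition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction and subtype quantification for cortical
    pyramidal neurons.  Implements current-clamp analysis of the passive
    membrane (I-V curves, peak and steady-state input resistance, sag,
    time to peak), spike-train analysis (dV/dt-interpolated firing
    threshold, action-potential waveform features, fast and medium
    afterhyperpolarizations and depolarizing afterpotentials with
    doublet/triplet burst handling, rheobase, f-I curves, interspike
    interval adaptation), k-means++ clustering of standardized
    morphometric feature tables with silhouette-based selection of the
    cluster number, and laminar-bin counting of marker co-expression
    with per-animal composition statistics.  Ground-truth synthetic
    generators for voltage traces, morphology mixtures, and laminar
    cell maps make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
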