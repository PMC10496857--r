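Package: muellerpol
Title: Mueller-Matrix Image Decomposition for Tissue Polarimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pixel-wise analysis of 4x4 Mueller-matrix images of thin
    birefringent tissue sections measured in transmission. Implements
    Cloude physical-realizability filtering of measured matrices, the
    differential (matrix-logarithm) decomposition with Minkowski-metric
    split into polarizing and depolarizing generators, and the forward
    Lu-Chipman polar decomposition into diattenuator, retarder and
    depolarizer factors, together with per-image maps and box-whisker
    summaries of scalar retardance, optical-axis azimuth and
    depolarization. A forward simulator of one- and two-layer stacks of
    birefringent, depolarizing tissue stripes (with spatial
    heterogeneity, holes and detector noise) provides ground truth for
    every pipeline stage, emulating crossed nerve-fiber geometries such
    as stacked corpus callosum sections.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
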