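Package: caflux
Title: Analysis of Astrocytic and Neuronal Calcium Imaging During Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for two-photon calcium imaging of cortical astrocytes
    and neurons in behaving mice. Implements temporal binning, rigid motion
    correction driven by the autofluorescence channel, Anscombe/patch-SVD
    denoising, pixel-wise dF/F with a lower-envelope baseline and mode bias
    correction, active-area event detection, astrocyte soma/process latency
    and Morlet wavelet band-power analysis, patch-based non-negative
    factorization of neuronal movies into activity units, and
    locomotion-coupling statistics (Q/L ratio, cross-correlation lag,
    paired-run ratio, Mann-Whitney U). A synthetic-movie generator with full
    ground truth provides parameter-recovery tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
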