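Package: atriarecon
Title: Non-Model-Based Left Atrial Volumetry from Sparse Cine MR Slice Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a closed three-dimensional left-atrial surface and its
    volume from a handful of arbitrarily oriented 2D cine MR slice contours, by
    interpolating a per-plane inside/outside indicator function into space and
    extracting its zero level set as a watertight triangle mesh. Includes the
    model-based bi-plane area-length comparator, left-atrial time-volume curves
    and functional indices (reservoir, conduit and booster function), synthetic
    left-atrial phantoms with analytic reference volumes and configurable slice
    orientation strategies, Bland-Altman agreement statistics, repeated-measures
    ANOVA for orientation-by-method interaction, and an endocardial border
    sharpness metric.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    EBImage,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
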