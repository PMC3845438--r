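Package: vesselgrow
Title: Spectrum-Guided Branch-Based Region Growing for Vessel Segmentation
Version: 0.1.0
Authors@R: person("vesselgrow", "developers", role = c("aut", "cre"),
    email = "vesselgrow@example.org")
Description: Segments bright tubular (vascular) structures in 2D images and
    3D volumes. Combines multiscale Hessian vessel enhancement with
    max-over-scales fusion, Fourier-domain tubular-structure detection and
    orientation estimation via angular spectral energy, fully automatic
    seed selection from Sobel edges and matched-filtered cross-sections,
    and a branch-based seeded region-growing algorithm with LIFO branch
    deferral, connectivity-based bifurcation detection and dynamic
    per-branch gray-level thresholds. Includes a synthetic vascular
    phantom generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
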