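Package: safsheet
Title: Geometry and Retinotopic Topography of Short Association Fibre Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of diffusion MRI tractography for short
    association fibres (SAF) beneath the V1-V2 cortical interface.
    Reads streamline tractograms (TCK) and cortical surface meshes with
    per-vertex retinotopic maps, conditions phase-encoded fMRI maps
    (spectral signal-to-noise statistic, reliability masking, iterative
    neighbourhood smoothing, V1/V2 label-overlap resolution), selects
    V1-V2 connecting streamlines, computes per-streamline geometry
    (arc length, apex, bending angle, intracortical fraction, deep
    white-matter exclusion), characterises the fibre population as a
    sheet (principal frame, per-axis variances, 2D surface fit,
    sheet-versus-bundle classification), projects retinotopy onto
    streamlines, clusters them into topographic bands, and quantifies
    topographic order.  Includes a synthetic folded-gyrus phantom
    generator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
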