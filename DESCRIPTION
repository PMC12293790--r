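Package: spotcall
Title: Marker Positivity Annotation of Multicellular Spatial Transcriptomics Spots from Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates Visium-style multicellular capture spots as positive or
    negative for a nuclear immunofluorescence marker (for example gamma-H2AX)
    from whole-slide RGB images. Nuclei are segmented inside each 55 micron
    spot by iterative DAPI-threshold peeling, which separates overlapping
    nuclei by raising the threshold step-wise and accepting connected regions
    whose boundary length fits a perimeter limit. Marker-positive pixels are
    defined by per-channel RGB minimum/maximum thresholds, cells by the
    fraction of positive pixels in their nucleus, and spots by user-set
    intensity and percent-positivity rules with a minimum-cell filter.
    Includes inter-rater agreement statistics (pairwise percent agreement and
    Fleiss' kappa), a Loupe-Browser-importable category export, and a
    synthetic slide generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
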