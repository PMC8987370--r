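Package: prolifscape
Title: Proliferation Landscapes and Pulse-Chase Fate Maps Along the Amphioxus Neural Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial distribution of cell proliferation along
    the anteroposterior axis of developing amphioxus embryos. Implements the
    proliferation "landscape" statistic (axis-normalised 20 micron binning of
    EdU- and PhH3-positive nuclei, averaged per embryo cohort), pulse-chase
    fate-map profiles in evenly sized axial bins per tissue, and clone-extent
    statistics (floor-plate coverage, labelled posterior somite counts). An
    agent-based synthetic-embryo simulator generates staged cohorts with
    stage-dependent proliferative domains, heritable EdU labelling, and
    hydroxyurea division arrest, providing ground-truth inputs for the whole
    pipeline. A minimal imaging stage renders simulated embryos as 3D stacks
    and recovers nuclei by DAPI masking and connected-component detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
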