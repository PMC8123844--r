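Package: nucleoprofile
Title: Quantification and Classification of Nuclear Marker Activity Profiles
    in Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nucleus-level quantification of two-channel fluorescence
    microscopy images of plant root meristem nuclei: segmentation of nucleus,
    nucleolus and heterochromatin from a chromatin (DAPI-like) channel,
    detection and measurement of marker-channel foci, rule-based assignment
    of five nuclear activity profiles (including perinucleolar ring scoring),
    and an expectation-maximization Dean-Jett-Fox mixture fit for phase
    fractions from univariate DNA-content samples.  A synthetic two-channel
    nucleus-image generator with full ground truth supports parameter-recovery
    testing of every stage, emulating hydroxyurea (replication-stress) and
    caffeine co-treatment (premature chromosome condensation) effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
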