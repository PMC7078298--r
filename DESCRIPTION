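Package: gliaquant
Title: Quantification of Retinal Microglial Activation from Fluorescence Whole-Mounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microglial activation in retinal
    whole-mount fluorescence images: threshold/centroid/minimum-distance
    cell counting in the plexiform layers, Iba-1 area fraction, soma and
    arbor morphometry, vertical-process (punctum) counting, and P2RY12
    mean-intensity measurement, together with a synthetic whole-mount
    generator with exact ground truth and the nonparametric group
    comparison scheme (Wilcoxon, Mann-Whitney, ANOVA with Bonferroni
    correction) used in ocular-hypertension time-course studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
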