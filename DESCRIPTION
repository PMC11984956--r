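Package: centriolr
Title: Quantification Pipelines for Centriolar Distal-Appendage Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification steps used in
    fluorescence studies of the centriole's distal appendages and early
    ciliogenesis: semi-automated centrosomal and ciliary intensity measurement
    with robust (ROUT) outlier flagging, peak-to-peak diameter measurement of
    ninefold appendage rings with a molecular-ruler model for epitope offsets,
    post-processing of two-colour 3D single-molecule localization data (fiducial
    drift correction, quality filtering, affine channel registration with
    iterative 3D cross-correlation refinement, cluster sizing and centre-of-mass
    offsets), categorical assay scoring (ciliation, preciliary-vesicle
    positivity, CP110 removal), and the matching statistical layer (Welch and
    nested t-tests, nested one-way ANOVA with Monte-Carlo Dunnett comparisons,
    Fisher's exact test, ROUT). Synthetic-data generators with ground truth make
    every stage testable without microscope data.
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
    graphics,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
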