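Package: subaxis
Title: Anterior-Posterior Parcellation of Hippocampal Subfield Masks and
    Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Divides a binary 3-D hippocampal-subfield mask into equal-length
    volumetric segments along its anterior-posterior axis (farthest
    surface-voxel pair, projection binning), and provides the downstream
    statistics used in subfield biomarker studies: per-segment z-scoring and
    3-SD quality control, a two-component Gaussian-mixture cutoff for bimodal
    CSF amyloid-beta 42, fixed P-tau cutoffs, memory-error binning, split-plot
    repeated-measures ANCOVA with a segment-by-group interaction, partial
    correlations, and pairwise post hocs. Includes tube-phantom and synthetic
    cohort generators so the whole pipeline is testable without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
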