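Package: fcparc
Title: Individual-Level Functional Connectivity Parcellation of Cortical Surface Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional network parcellations of a cortical surface
    region of interest from resting-state fMRI connectivity profiles and
    adapts them to single subjects. Provides spherical k-means clustering of
    vertex connectivity profiles with Dice/silhouette model-order selection,
    iterative confidence-weighted individualization of a group atlas,
    size-weighted connectional and task homogeneity metrics, Mantel
    permutation tests against anatomical similarity, and seed-based
    connectivity with permutation cluster-extent correction. Includes a
    synthetic surface-fMRI cohort generator with known ground-truth network
    layouts for end-to-end validation, and a command-line interface over the
    pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    igraph,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
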