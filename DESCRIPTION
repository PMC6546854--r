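Package: rsmvpa
Title: Resting-State fMRI Features, Wrapper Region Selection and Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-voxel pattern analysis of resting-state BOLD fMRI for two-condition
    within-subject designs. Computes three voxel-wise feature maps - regional homogeneity
    (Kendall's coefficient of concordance over 3x3x3 neighbourhoods), binary degree
    centrality of the voxel-wise correlation graph, and the fractional amplitude of
    low-frequency fluctuations - together with the surrounding temporal band-pass and
    spatial smoothing stages, aggregates them over an atlas parcellation into region
    vectors, selects discriminative region subsets by sequential forward (floating)
    selection wrapped around the leave-one-out cross-validated error of a linear
    support vector machine, and assesses significance by label-permutation testing.
    A synthetic BOLD cohort generator with known ground-truth condition effects makes
    the full pipeline testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
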