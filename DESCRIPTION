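Package: aphasiamorph
Title: Predicting and Subtyping Severe Post-Stroke Aphasia from Ordinal Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict severe post-stroke aphasia (Western Aphasia
    Battery aphasia quotient at or below 50) from 3D ordinal brain-morphometry
    volumes, compare a volumetric convolutional neural network against support
    vector machines under a shared preallocated nested stratified
    cross-validation plan, fuse model probabilities, explain predictions with
    Grad-CAM++ and Shapley-value saliency maps, and subtype individuals by
    consensus clustering of saliency maps with dip-test screening, PAC
    model-order selection and affinity-propagation exemplars. Includes a
    synthetic cohort generator with planted, total-matched spatial atrophy
    motifs so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    rlang,
    e1071,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS
Config/testthat/edition: 3
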