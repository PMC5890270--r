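Package: mmdnn
Title: Multiscale Patch Features and Multimodal Deep Neural Networks for
    Dementia Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Patch-based multiscale feature extraction from co-registered
    structural (T1 MRI) and metabolism (FDG-PET) brain volumes, and a
    multimodal multiscale deep neural network (MMDNN) classifier for
    staging progression towards Alzheimer's disease. Template gray-matter
    regions of interest are subdivided into patches of fixed voxel count
    by spatial k-means; patch volumes and brainstem-normalized mean
    metabolism form six feature sets (three scales, two modalities), each
    feeding a tied-weight stacked-autoencoder network whose latent codes
    are fused by a second network. Training follows greedy layer-wise
    pretraining, supervised fine-tuning with dropout and early stopping,
    and joint tuning; ensembles of ten networks with rotating validation
    splits vote by summed probabilities, and the positive-class
    probability serves as a disease staging score. Subject-level
    cross-validation experiment designs (stable versus progressive MCI,
    and controls versus an enriched dementia-positive class) and a
    synthetic staged-cohort simulator make the full pipeline runnable
    without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
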