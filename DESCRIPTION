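Package: LatentFaces
Title: Disentangled Generative Latent Encoding and Decoding of Face-Selective fMRI Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for interpreting simulated face-selective brain responses with
    disentangled deep generative models. Provides a procedural face generator with
    known independent factors, a simulator for voxel responses (repeat-averaged and
    HRF-convolved time-series forms) with known ground-truth encoding weights, a
    desk-scale beta-VAE / FactorVAE implementation with latent traversals and
    supervised disentanglement scoring, voxelwise encoding GLMs with latent-value
    regressors, combined selectivity-plus-reliability voxel selection,
    winner-take-all preference mapping, pseudo-inverse facial-identity decoding
    over dimension subsets, and permutation-based inference at the individual and
    group level.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    png,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
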