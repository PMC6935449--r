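Package: gmhcrf
Title: Full-Covariance Gaussian-Mixture Hidden Conditional Random Fields for Sequence Classification
Version: 0.1.0
Authors@R: person("gmhcrf", "maintainers", email = "gmhcrf@example.org", role = c("aut", "cre"))
Description: Discriminative classification of sequences of real-valued feature
    vectors (e.g. per-frame video descriptors in human activity recognition)
    with hidden conditional random fields whose emission potentials are
    log-densities of full-covariance Gaussian mixtures. Provides log-space
    forward/backward scoring, analytic gradients computed from cached
    forward/backward results, L-BFGS training over an unconstrained
    Cholesky/softmax parameterization, a Gaussian-HMM comparison model with an
    exact HCRF parameter mapping, a diagonal moment-feature HCRF baseline, a
    seeded GMM-HMM synthetic data generator, grouped k-fold cross-validation
    with confusion-matrix reports, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
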