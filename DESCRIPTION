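Package: goalddm
Title: Goal-Dependent Multi-Attribute Drift Diffusion Modelling and
    Multivoxel Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how regulatory goals reshape value-based
    choice. Implements a multi-attribute drift diffusion model with
    exponentially collapsing decision bounds, a deterministic
    transition-matrix likelihood, and per-subject maximum-likelihood
    fitting; behavioral scoring of healthy and altruistic choices and
    regulatory-success contrasts; synthetic generators for choice
    behavior and trial-wise voxel patterns with planted attribute codes;
    searchlight support-vector-regression decoding with leave-one-run-out
    cross-validation and Fisher-z accuracy maps; group-level inference
    with permutation-based cluster correction and conjunctions; and
    cross-subject leave-one-subject-out decoding of regulatory success
    with permutation tests.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    lhs,
    minqa,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
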