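Package: tcsfb
Title: Dichotomous Feedback Design and Analysis for Two-Component Signalling Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, analyses and simulates dichotomous feedback: negative
    feedback regulation of a bacterial two-component signalling system built
    by sequestering the pathway's own phosphotransfer flux, either with a
    second response regulator (phosphorylation sequestration) or with an
    added phosphatase (dephosphorylation enhancement). Provides mass-action
    reaction networks for the wild-type system, the open- and closed-loop
    sequestration architectures and the molecular-sequestration and
    transcriptional comparison feedbacks; deterministic simulation,
    steady-state and dose-response computation; closed-form steady-state
    approximations with validity diagnostics; stability, invariance and
    monotonicity checks; intrinsic-noise quantification by the linear noise
    approximation and an exact direct-method Gillespie simulator; sensitivity
    function (frequency-domain robustness) analysis; and crosstalk-reduction
    experiments with an extra histidine kinase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
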