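Package: biosensordbtl
Title: Mechanistic-ML Workbench for Context-Dependent Whole-Cell Biosensor Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design-Build-Test-Learn analysis workflow for naringenin-responsive
    whole-cell biosensors. Implements a context-dependent mechanistic ODE model
    of growth and GFP/OD reporter dynamics, weighted least-squares calibration
    with a hybrid global/local optimizer and bootstrap-bagged parameter
    ensembles, D-optimal experimental design over categorical genetic and
    environmental factors, machine-learning surrogates (support-vector
    regression and a small feed-forward network) that map encoded contexts to
    mechanistic parameters, and rank-based selection of biosensor designs for
    high gain or fast response with one-tailed Kendall validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    e1071,
    kernlab,
    lhs,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
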