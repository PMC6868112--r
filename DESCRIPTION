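Package: gctmod
Title: Glucagon Challenge Test Modeling and Receptor-Change Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and parameter estimation for a three-compartment
    glucose-insulin-glucagon turnover model coupled to glucagon-receptor
    binding, internalization and recycling kinetics, with Hill-type hepatic
    glucose production. Provides a seeded synthetic paired-cohort generator
    emulating a 6 h glucagon challenge test (3 h baseline steady state, 3 h
    somatostatin-clamped infusion), generalized-profiling (spline collocation)
    parameter estimation under steady-state constraints, and the paired
    before/after treatment analysis: exact Wilcoxon signed-rank tests,
    Benjamini-Hochberg FDR correction, and the relative receptor-number
    change inferred from the apparent dissociation constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    splines,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
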