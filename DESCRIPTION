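Package: mbdoe
Title: Model-Based Design of Experiments for Nonlinear ODE Kinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based design of experiments (MBDoE) with
    nonlinear ordinary-differential-equation kinetic models. Provides
    built-in Michaelis-Menten and reversible nucleoside-phosphorolysis
    models with temperature dependence, ODE simulation with forward
    parameter sensitivities, weighted least-squares parameter estimation
    with Latin-hypercube multistart, Fisher-information-based confidence
    ellipses (D-, E- and A-optimality), Monte-Carlo re-estimation
    ensembles for nonlinear confidence regions, a quantile-based design
    criterion (Q-criterion) robust to non-invertible information
    matrices, and optimization of sampling times under either family of
    criteria.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
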