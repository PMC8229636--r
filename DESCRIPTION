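Package: pcgeom
Title: Information Geometry of Exponential-Family Lifetime Models under
    Progressive Type-II Censoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for progressively Type-II censored life tests under
    exponential-family lifetime models: censoring-scheme algebra and the
    combinatorial coefficients of censored order-statistic marginals, exact
    censored-sample simulation, joint likelihood and score evaluation, the
    Fisher metric, skewness tensor, alpha-connections, torsion and
    Riemann-Christoffel curvature of the induced statistical manifold, and
    Laplace-type asymptotic expansions of Bayesian posterior and predictive
    densities with exact-quadrature and conjugate-form cross-checks.
    Built-in Rayleigh, exponential and Gamma models, a simulation harness
    for comparing plug-in and Bayesian prediction, and a packaged
    insulating-fluid breakdown data set.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
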