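Package: addseries
Title: Addition-Series Analysis of Plant Competition Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Design, simulate and analyse addition-series competition
    experiments on per-plant biomass. Fits hyperbolic yield-density models
    by nonlinear least squares on the natural-log scale, estimates
    intraspecific and interspecific competition coefficients for two-species
    (biculture) stands, derives the neighbour densities at which per-capita
    biomass declines by a stated fraction (with parametric-bootstrap
    confidence intervals), and computes relative competitive ability and its
    density-equivalence interpretation. A synthetic experiment generator
    with binomial plant mortality and multiplicative lognormal biomass noise
    supports parameter-recovery and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
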