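Package: il27sim
Title: Spatial Modeling of IL-27-Induced Anti-Tumor CD8+ T Cell Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a radially symmetric reaction-diffusion model of the
    tumor microenvironment in which IL-27, secreted by transfected tumor cells
    or delivered by injection, modulates CD8+ T cell survival and the secretion
    of the anti-tumor cytokines IL-10 and interferon-gamma.  Provides a
    conservative finite-volume method-of-lines solver on a ball, continuous and
    intermittent IL-27 injection protocols with matched cumulative dose,
    closed-form two-time-point estimators that recover kinetic parameters from
    genotype-contrasted mouse experiments, a synthetic observation generator
    for end-to-end recovery studies, and Latin hypercube / partial rank
    correlation coefficient sensitivity analysis of the treated-to-control
    tumor ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
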