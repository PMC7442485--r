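Package: tpcniche
Title: Fundamental and Realized Thermal Performance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how interspecific competition reshapes thermal
    performance curves (TPCs). Implements a mechanistic model of fundamental
    TPCs (Gaussian cold limb, quadratic warm limb, hard upper critical
    temperature), Gaussian temperature-weighted performance, and realized TPCs
    defined as the relative performance of two competitors; an inference
    pipeline for binomial thermal-performance data (quadratic-logit GLMs and
    GLMMs with plot and year random intercepts, optimal-temperature extraction
    from the fitted vertex, breadth from pointwise 95% confidence bands,
    likelihood-ratio tests, parametric bootstrap uncertainty); and synthetic
    generators that emulate common-garden and elevational field experiments on
    burying beetles competing with blowflies, so the whole analysis can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
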