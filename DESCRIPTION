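Package: osteodyn
Title: Data-Driven ODE Models of Trabecular Bone Injury Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation models of osteoblast, osteoclast
    and bone-volume dynamics during trabecular bone injury repair, including a
    variant in which per-cell remodeling activity is modulated by imposed
    pro- and anti-inflammatory myeloid (monocyte/macrophage) time courses and a
    variant with piecewise-linear time-varying resorption or formation rates.
    Provides the full calibration machinery: a minimax weighted least-squares
    objective, penalized Nelder-Mead simplex search with seeded multi-start,
    AIC model comparison, staged fitting workflows (cell dynamics, constant
    rate scans, free constant rates, myeloid modulation, piecewise rates),
    bootstrap standard errors, goodness-of-fit diagnostics (per-variable R2,
    standardized residual counts, activity fold ranges) and a synthetic
    time-course generator emulating a sparsely sampled replicated study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
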