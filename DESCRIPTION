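Package: behavmet
Title: Linking Resting Metabolic Rate to Memory, Personality and Dominance in Small Animal Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies relating resting metabolic rate to
    behavioural traits in small groups of animals, built around juvenile-chicken
    study designs. Computes oxygen consumption and carbon dioxide production from
    open-flow respirometry traces with ambient baseline drift correction and
    stable-window selection; scores radial-arm-maze trials against Monte Carlo
    null models of random and stereotypic arm choice; estimates repeatability
    (intraclass correlation) of censored latency traits with likelihood-ratio
    tests and parametric bootstrap intervals; ranks individuals by David's score
    from winner-loser matrices; and applies an AIC-based model selection rule to
    negative binomial, linear mixed, accelerated failure time and linear models.
    A synthetic-data module generates every input the pipeline consumes, with
    ground-truth metadata, so the full chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
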