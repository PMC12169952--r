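Package: eatcost
Title: Diet Cost and Adherence to the EAT-Lancet Reference Diet from
    Repeated 24-h Dietary Recalls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating how daily diet cost varies with adherence
    to the EAT-Lancet reference diet from repeated 24-h dietary recalls.
    Implements sales-weighted food-group pricing with yield adjustment and
    a fallback hierarchy for unpriced groups, linkage of recall amounts to
    daily diet costs, a declarative EAT-Lancet dietary index (EAT-I, 0-80
    points) scoring engine, energy-misreporting plausibility screening,
    a multivariate measurement-error model for episodic and daily dietary
    variables (two-part Box-Cox mixed model fitted by Markov chain Monte
    Carlo with Monte Carlo simulation of pseudo-individuals), restricted
    cubic spline regression of usual diet cost on index scores with
    percentile contrasts and bootstrap confidence intervals, and a
    synthetic-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
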