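Package: entroread
Title: Cloze Entropy, Activation Decay, and Bayesian Reading-Time Models
    for Long-Distance Verb-Particle Dependencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lexical predictability in long-distance
    dependencies such as German particle verbs. Computes cloze
    probabilities and Shannon entropy from cloze-norming responses,
    simulates locality/antilocality reading-time predictions from an
    ACT-R style activation-decay model, derives standard eye-movement
    reading measures (first fixation duration, first-pass reading time,
    total fixation time, regression path duration) from fixation
    sequences, fits Bayesian hierarchical reading-time models with
    crossed participant/item random effects on reciprocal or log scales,
    and compares full against reduced models with bridge-sampling Bayes
    factors across a range of effect priors. Includes a synthetic-data
    generator (Latin-square designs, cloze tables, self-paced reading
    and eye-tracking trials) so the full pipeline can be exercised and
    validated without any participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mvtnorm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lme4,
    knitr,
    ggplot2
Config/testthat/edition: 3
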