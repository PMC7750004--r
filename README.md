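# entroread

Cloze entropy, activation decay, and Bayesian reading-time models for
long-distance verb–particle dependencies.

## The problem

German particle verbs split into a base verb and an obligatory particle
that often appears only at the right clause boundary ("Er **räumte**
den Raum **auf**" — *he tidied the room up*). When the base verb is
read, does the reader pre-activate the set of plausible particles, so
that a verb licensing few particles (a *small set*) makes the eventual
particle more predictable than one licensing many (*large set*)? And
what does delaying the particle with neutral material do — sharpen the
expectation and speed reading (*antilocality*), or let the particle's
activation decay and slow reading (*locality*)?

`entroread` is for psycholinguists running or simulating this kind of
reading study. It provides:

* **Cloze statistics** — per item×condition cloze probabilities, target
  cloze, and Shannon entropy $H = -\sum_i P_i \log_2 P_i$ (bits) from
  norming responses, with Beta/bootstrap condition summaries,
  median splits, and norming-based item selection.
* **An activation-decay simulator** — a finite pool of spreading
  activation $W$ split over $n$ candidate particles with power-law
  decay $d$ and latency $T = F\,t^{d} e^{-W/n}$, generating the 2×2
  locality/antilocality predictions in closed form.
* **Eye-movement measures** — first fixation duration, first-pass
  reading time, total fixation time, and regression path duration for
  a (merged) target region from fixation sequences, with blink/track-
  loss exclusion.
* **Bayesian hierarchical reading-time models** — reciprocal-speed
  (self-paced) and log-ms (eye-tracking) regressions with ±0.5 effect
  coding, crossed participant/item random effects with full covariance
  matrices, half-Normal scale priors and LKJ(2) correlation priors,
  sampled by a compiled blocked Gibbs sampler; Box–Cox transform
  selection and prior-predictive arithmetic included.
* **Bayes factors** — bridge-sampling marginal likelihoods on a
  collapsed posterior, full vs. reduced comparisons per predictor at
  three effect-prior widths (0.1 / 0.5 / 1.0) with 3.0 / 0.3 evidence
  thresholds, validated against a conjugate-Normal analytic oracle.
* **A synthetic-data generator** — Latin-square designs, cloze tables,
  self-paced and eye-tracking trials with the statistical structure
  the analyses assume, so the whole pipeline runs without any
  participant data.

## Worked example

Entropy of a cloze distribution with nine "vor" and one "an":

```r
library(entroread)
rs <- cloze_response_set("item01", "small", "short",
                         completions = c(vor = 9, an = 1),
                         is_particle = c(vor = TRUE, an = TRUE))
compute_cloze_statistics(rs, target = "vor")
#> Cloze statistics for item item01 (small set, short distance)
#>   target 'vor': cloze 0.900 | entropy 0.469 bits | 2 particle types
```

The cloze probability 0.9 says most respondents produced the target;
0.47 bits is low entropy, i.e. a predictable particle. The decay
simulator turns memory assumptions into the predicted 2×2 pattern:

```r
predict_design(decay_config(), n_small = 4, n_large = 14)
#> Predicted retrieval latencies (ms) under activation decay
#>  set_size distance latency_ms
#>     small    short   241.3026
#>     large    short   288.4793
#>     small     long   278.6322
#>     large     long   333.1071
#> locality cost (long - short): small set 37.3 ms, large set 44.6 ms
#> interaction (large - small locality cost): 7.3 ms
```

Small-set particles are faster everywhere, and the cost of added
distance is larger for the large set — the crossing pattern that
separates decay from surprisal-style antilocality. Simulating a full
60-participant × 24-item self-paced experiment with a planted set-size
effect of +0.07 words/s and fitting the hierarchical model:

```r
design <- experiment_design(n_participants = 60, n_items = 24, seed = 1)
trials <- generate_spr_trials(design,
            generative_params("reciprocal_speed", beta = c(set_size = 0.07)),
            seed = 2)
fit <- fit_reading_model(trials, predictors = "categorical",
                         prior = prior_spec("reciprocal_speed"), seed = 3)
fit
#> Bayesian hierarchical reading-time model (reciprocal_speed)
#>            parameter   mean ci_low ci_high  rhat  ess
#>          b_Intercept  2.502  2.391   2.615 1.000 4000
#>           b_set_size  0.068  0.004   0.132 1.000 4000
#>           b_distance  0.035 -0.025   0.098 0.999 3867
#>  b_set_size:distance -0.011 -0.137   0.118 1.000 3966
#>                sigma  0.500  0.481   0.520 1.004  822
```

On the reciprocal scale a positive slope means faster reading: the
planted +0.07 words/s advantage for large-set items is recovered
(posterior mean 0.068, 95% CrI [0.004, 0.132]), the null distance
effect straddles zero, and the intercept sits at the generating
2.5 words/s (≈ 400 ms). Bayes factors for any predictor come from
`bf_predictor_table()`, or at a lower level from
`estimate_log_marginal_likelihood()` + `bayes_factor_ratio()` on a
full and a reduced fit. `run_pipeline(default_config())` chains every
stage — norming simulation, statistics, decay predictions, reading
simulations, exclusions, fits — and writes the report tables as CSV;
`inst/cli/entroread.R` wraps the same functions for shell use.

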