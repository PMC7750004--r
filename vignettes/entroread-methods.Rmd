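---
title: "Models and methods in entroread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in entroread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroread)
```

# The scientific problem

When a reader encounters a German particle verb such as *räumte … auf*
("tidied … up"), the base verb commits the sentence to an obligatory
particle whose lexical identity may only be revealed at the end of the
clause. Two questions follow. First, do readers pre-activate the set of
plausible particles when the base verb is read — so that a verb
licensing only a few particles ("small set") yields a more predictable,
faster-read particle than one licensing many ("large set")? Second,
what does delaying the particle do: sharpen expectations and speed
reading (an antilocality effect, as surprisal accounts predict), or let
the particle's pre-activation decay and slow reading (a locality
effect, as activation-based memory models predict)?

`entroread` implements the quantitative machinery this kind of study
needs: predictability scoring from cloze norming (probabilities and
Shannon entropy), an activation-decay simulator that turns memory-model
assumptions into a 2×2 reading-time prediction, eye-movement reading
measures, Bayesian hierarchical reading-time models on the two standard
transforms, and Bayes-factor model comparison across a range of effect
priors. A synthetic-data generator produces designs and datasets with
the statistical structure the analyses assume, so every stage is
testable end to end without any participant data.

# Cloze statistics

Respondents complete a truncated sentence; completions are counted per
item and condition. With cloze probabilities $P_i$ over the particle
completions, predictability at the particle site is summarized by the
target particle's cloze probability and by the Shannon entropy

$$H = -\sum_i P_i \log_2 P_i \quad \text{(bits)},$$

so that $H = 0$ when a single particle is ever produced and
$H = \log_2 k$ when $k$ particles are produced equally often. A
distribution of nine "vor" and one "an" gives
$-(0.9\log_2 0.9 + 0.1\log_2 0.1) = 0.47$ bits.

Choices the norming literature leaves open, and what this package does:

* **Probability universe.** Non-particle completions are excluded from
  the universe by default — predictability *of the particle* is the
  quantity of interest — with `particle_only = FALSE` available for
  sensitivity analyses.
* **Completion normalization.** Strings are trimmed, lower-cased, and
  truncated to their first token; orthographic cleanup beyond that is
  out of scope.
* **Condition summaries.** Per-item target-cloze values are summarized
  by a method-of-moments Beta fit, reporting the fitted mean and the
  2.5%/97.5% Beta quantiles. This reading — an interval of the cloze
  probability *distribution* — is deterministic and reproducible.
  Entropy has no comparable standard family, so its interval is a
  nonparametric bootstrap over items (2,000 resamples, fixed seed).
  Across-items intervals are the default; across-respondent variation
  is accessible by summarizing the response sets directly.
* **Median splits.** Used for descriptive tables only. Ties at the
  median go to `low`, which keeps the split deterministic; the
  continuous value is what enters any model.
* **Item selection.** An item passes norming when every condition
  elicited at least one particle and the large-set condition elicited
  strictly more particle types than the small-set condition within each
  distance level; per-item reasons are reported for the rest.

# The activation-decay simulator

The simulator formalizes the decay hypothesis with the standard
activation-based ingredients. A finite pool of spreading activation $W$
is divided equally among the $n$ plausible particles, so each candidate
starts with $W/n$ activation above baseline — small sets mean stronger
pre-activation per particle. Base-level activation decays as a power
function of the time $t$ since pre-activation, and retrieval latency is
exponential in total activation:

$$A(n, t) = \ln(t^{-d}) + W/n, \qquad T(n, t) = F e^{-A} = F\,t^{d} e^{-W/n}.$$

The closed form makes the predicted interaction transparent: the
locality cost $T(n, t_{long}) - T(n, t_{short}) =
F\,e^{-W/n}(t_{long}^d - t_{short}^d)$ is strictly increasing in $n$,
so the slow-down from added distance should be visible mainly when the
candidate set is large — the crossing pattern that distinguishes decay
from surprisal-style antilocality (where distance always helps).

Parameters, units, and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `decay_rate` (d) | power-law decay exponent | 0.5 | the conventional ACT-R value |
| `pool` (W) | spreading-activation budget | 1 | one unit shared across candidates |
| `latency_factor` (F) | latency scaling, ms | 200 | puts latencies in a reading-time range |
| `t0` | elapsed time before intervening words, s | 0.4 | roughly one word-reading time |
| `k_word` | elapsed time per intervening word, s | 0.4 | typical word-reading time |
| `words_short`, `words_long` | intervening words | 5, 7 | object NP vs. object NP plus a two-word modifier |

Only the relative, qualitative pattern is contractual; absolute
millisecond values move with the configuration. The simulator
deliberately omits retrieval interference, cue overlap, and any race
between candidates: distance is manipulated with material that adds no
interference, so decay is the only mechanism in play, and fitting the
simulator to data is a non-goal.

# Eye-movement reading measures

From an ordered fixation sequence, for a target region (by default the
merged span of the particle and the word before it, since two- or
three-letter particles are frequently skipped):

* **FFD** — duration of the first first-pass fixation on the region;
* **FPRT** (gaze duration) — summed fixations from first entering the
  region until first leaving it in either direction;
* **TFT** — all fixations on the region over the whole trial;
* **RPD** (go-past) — summed fixations from first entry until the
  first fixation strictly to the right, regressive fixations included.

Conventions the verbal definitions leave open: a region first fixated
only after material to its right counts as skipped in first pass (FFD,
FPRT, and RPD are missing; TFT still accumulates); when nothing to the
right is ever fixated, RPD runs to the end of the trial and is flagged
`rpd_unterminated`; a first-pass fixation on either word of the merged
span counts as fixating the region. On every non-skipped trial
FFD ≤ FPRT ≤ TFT and FPRT ≤ RPD. Trials flagged for blinks or track
loss are excluded before any measure is computed, with counts logged.

# Hierarchical reading-time models

Reading times are modelled on the scale a Box–Cox profile supports:
self-paced reading times as reciprocal speed ($1000/\mathrm{rt}$,
words/second), eye-tracking measures as $\log \mathrm{rt}$.
`select_boxcox_lambda()` profiles $\lambda$ over the grid
$-2, -1.9, \dots, 2$. Self-paced reading times below 100 ms are
excluded as recording artefacts before fitting.

The regression has the 2×2 design's fixed effects under ±0.5 effect
coding (so slopes are main effects at the grand mean), or mean-centered
entropy crossed with distance for the continuous analysis, plus crossed
participant and item random effects with intercepts, all slopes, and
full covariance matrices. Priors on the reciprocal scale: intercept
$\mathcal N(3, 0.5)$ (mean speed near three words/second, 95% within
two and four), slopes $\mathcal N(0, 0.5)$, random-effect and residual
SDs half-$\mathcal N(0, 0.25)$, correlations LKJ(2). On the log scale:
intercept $\mathcal N(5.7, 0.5)$ (about 300 ms, 95% within 110–812 ms),
slopes $\mathcal N(0, 0.5)$ (a plausible effect at most a ~190 ms
speed-up to a ~513 ms slow-down), scale priors half-$\mathcal N(0, 1)$.
`prior_predictive_bounds()` reproduces this arithmetic; endpoint values
are rounded half-up to integers on the response scale, which is why the
published integers can differ by a millisecond from the unrounded
differences.

Entropy is mean-centered by default (`center_entropy = FALSE` restores
the raw scale); centering changes only the intercept's meaning, but
that change matters when comparing intercepts across analyses.

## Sampling

The posterior is sampled by a blocked Gibbs scheme written for this
model family (compiled, with a pure-R reference implementation tested
against it):

* regression coefficients and each group's random-effect vector have
  conjugate multivariate-Normal updates;
* the fixed effects are updated with the item effects integrated out
  analytically (a partially collapsed update — the item blocks of the
  collapsed precision are block-diagonal, so this is cheap), and the
  residual scale is slice-sampled twice per scan, once with the item
  effects and once with the participant effects integrated out, the
  collapsed block being redrawn from its full conditional immediately
  after each update;
* two likelihood-invariant "sweep" moves — one between the fixed
  effects and the participant-effect means, one between the two
  random-effect blocks — remove the posterior ridges that otherwise
  dominate the autocorrelation of crossed designs;
* SDs and correlations are slice-sampled component-wise on an
  unconstrained scale: log SDs, and correlation matrices through
  canonical partial correlations (each Beta-distributed under LKJ, so
  the prior density on that scale is exact and fully normalized).

Defaults are 4 chains of 1,000 warmup plus 1,000 kept draws, seeded per
chain from the fit seed. Convergence is checked with the split-chain
potential-scale-reduction statistic at 1.01 for all reported
parameters, plus an autocorrelation-based effective sample size; a fit
that fails the check is returned but flagged, a warning is raised, and
the Bayes-factor stage refuses flagged fits. At a few hundred kept
draws this diagnostic has sampling noise of order 0.01, so borderline
flags at short test-scale chains are expected and are resolved by
running longer chains rather than by loosening the threshold.

## Cloze and entropy models

Per-item target cloze lives in $[0,1]$ with genuine mass at both ends,
so it is modelled with a zero/one-inflated Beta likelihood:
$p(0) = \alpha(1-\gamma_1)$, $p(1) = \alpha\gamma_1$, and
$(1-\alpha)\,\mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ on the interior, with
$\mathrm{logit}\,\mu$ linear in the coded predictors and
$\mathcal N(0, 0.25)$ slope priors. Entropy is non-negative with exact
zeros (single-completion items), hence a hurdle-lognormal:
$p(0) = \theta$, positive values lognormal with a linear location and
$\mathcal N(0, 0.01)$ slope priors. That prior is extremely tight — it
shrinks slopes essentially to zero — and is implemented as specified
with `prior_slope_sd` exposed for sensitivity analyses, because whether
so strong a regularizer is intended cannot be decided from the analysis
description alone. Remaining priors are weakly informative and
documented in the help pages: uniform on the boundary probabilities,
$\mathcal N(0,1)$ on intercepts, half-$\mathcal N(0,10)$ on $\phi$,
half-$\mathcal N(0,1)$ on the lognormal scale. Both models are sampled
by component-wise slice sampling, which at these dimensions yields
near-independent draws.

# Bayes factors

Evidence for each predictor is the Bayes factor
$\mathrm{BF}_{10} = \exp(\log ML_{full} - \log ML_{reduced})$ between
the full model and a reduced model without that predictor's fixed
effect. Because the Bayes factor is sensitive to the effect prior, the
comparison is run at three slope-prior widths — informative
$\mathcal N(0, 0.1)$, planned $\mathcal N(0, 0.5)$, diffuse
$\mathcal N(0, 1)$ — with 3.0 and 0.3 as the decision thresholds and
the conventional graded labels beyond them. No correction for
multiplicity across measures is applied; the output is per measure and
should be read as exploratory.

Design choices:

* **Reduced models keep the dropped effect's random slopes**, so the
  comparison concerns the population-level effect, not the random
  structure; dropping the slopes as well is available by fitting with a
  modified design.
* **Marginal likelihoods come from bridge sampling** (the iterative
  optimal-bridge estimator with a moment-matched Normal proposal,
  tolerance $10^{-6}$, at most 1,000 iterations). Half the posterior
  draws fit the proposal moments, the other half enter the bridge; the
  reported Monte-Carlo error is the spread of bootstrap re-estimates,
  and estimates with error above 0.5 nats carry a warning into the
  resulting Bayes factor.
* **The bridge operates on a collapsed posterior.** For the
  hierarchical models, the regression coefficients and all random
  effects are Gaussian given the variance parameters, so they are
  integrated out analytically (Woodbury identity on the low-rank
  covariance). What remains is the ~21-dimensional posterior of the
  residual scale, random-effect SDs, and correlations — whose Gibbs
  draws are, by construction, draws from exactly that collapsed
  posterior. Bridge sampling in ~21 dimensions with a moment-matched
  proposal is accurate; bridging the full ~350-dimensional augmented
  posterior would not be.
* **Oracle gating.** The estimator is validated against the
  closed-form marginal likelihood of a conjugate Normal-mean model
  (itself cross-checked by quadrature) before it is used anywhere else;
  the same oracle exhibits the expected Occam behavior — on null data,
  widening the slope prior lowers $\mathrm{BF}_{10}$.

# The synthetic-data generator

The generator emulates the study conditions the analyses assume, and
its defaults are those conditions: 60 participants × 24 items in a 2×2
(set size × distance) Latin square over four lists, six trials per
condition per participant, 72 fillers; a 48-item norming study with 63
fillers (111 sentences per list) and 31 respondents per item-condition;
comprehension accuracy 0.93 (the observed range is roughly 91–97%);
mean reading speed 2.5 words/s on the reciprocal scale and 5.7 log-ms
on the log scale, with residual and random-effect SDs chosen to put
simulated condition means and intervals in the published range
(~420–450 ms self-paced, ~280–320 ms first fixations).

Structure worth noting:

* **Cloze responses** are multinomial draws over a verb's particle
  inventory with Dirichlet-distributed probabilities; the symmetric
  concentration tunes entropy continuously from near-0 (one dominant
  particle) to $\log_2 k$ (uniform). Small-set inventories hold fewer
  than six particles and large-set more than ten (defaults 4 and 14),
  non-particle completions occur at a configured rate, and a configured
  8% of items get a designated target that is not the modal particle —
  a rate, not a rule, because the matching of targets across conditions
  that produced those items in norming practice is not reducible to the
  counts alone.
* **Per-item entropy** is drawn from two overlapping truncated-normal
  components (means 1.10 and 1.20 bits, SD 0.40), so both set-size
  categories contain high- and low-entropy items while the large-set
  mean is slightly higher — the configuration that motivates treating
  entropy, not set-size category, as the predictor of interest.
* **Self-paced reading** draws speed on the words/second scale from
  the full hierarchical model, maps it through $1000/\mathrm{speed}$,
  resamples the rare draws at or below 0.1 words/s, and replaces a
  configured 1% of trials with uniform 30–99 ms values so the
  exclusion rule has work to do.
* **Eye-tracking measures are built compositionally** — FPRT adds a
  refixation to FFD with probability 0.3, TFT adds re-reading with
  probability 0.25, RPD adds regression time with probability 0.2 — so
  the containment relations hold by construction rather than by hoping
  four correlated lognormals land in the right order. A 10% of trials
  skip the region in first pass; 5% carry blink flags. On request the
  generator also emits full fixation sequences that reproduce the
  generated measures exactly when re-derived, which is how the measure
  module is tested end to end.
* All randomness flows through one seeded generator per stage, with
  stage seeds derived from a master seed; generated tables carry their
  seed as an attribute.

What the generator does not emulate — and hence what passing tests do
not show about real data: no actual German lexical material (items are
abstract identifiers), no spillover or sentence wrap-up dynamics, no
saccade-level eye-movement control (fixation sequences are schematic
walks), no item-level confounds such as base-verb frequency, and no
dependence of question accuracy on the manipulation. Recovery results
certify the estimation machinery under the model's own assumptions,
not the assumptions themselves.

# Numerical choices and degenerate inputs

Zero- or negative-duration fixations, negative counts, probabilities
outside $[0,1]$, and non-positive reading times on the log scale are
rejected with validation errors rather than silently cleaned. A single
participant or single item is refused by the model stage (crossed
random effects are not estimable), zero-variance summaries collapse
their intervals to the mean with a warning, and Bayes factors refuse
marginal likelihoods computed on different data (checked by a data
fingerprint). Entropy terms with $P_i = 0$ contribute zero. Beta
method-of-moments fits fall back to the degenerate-interval path when
the variance bound makes the fit infeasible.

Problem sizes used in the package's own validation were chosen to keep
the full suite comfortably reproducible on a single CPU: the measure
oracle enumerates all 625 four-fixation sequences and checks
containment on ~10,000 generated trials; parameter-recovery runs use
20 simulated datasets per response scale at the full 60 × 24 design
with 2 chains × (300 + 400) draws; the acceptance script repeats a
10-dataset version and one planted-effect fit. The bridge estimator is
validated on conjugate models with 2,000 posterior draws.

# Known limitations

* The activation-decay simulator is a single-mechanism caricature by
  design; it cannot adjudicate between decay and interference, only
  translate the decay hypothesis into a testable pattern.
* The Gibbs sampler covers the Gaussian likelihoods this workflow
  needs; it is not a general-purpose probabilistic-programming
  replacement, and the ZOIB/hurdle models deliberately omit random
  effects (they model per-item summaries, one value per item and
  condition).
* Split-chain diagnostics at short chain lengths are noisy; the 1.01
  gate is strict by construction and favors false alarms over missed
  non-convergence.
* Marginal likelihoods for the hierarchical models are exact up to
  bridge-sampling error only relative to the stated priors; comparing
  them across different random-effect structures is not supported.
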