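---
title: "Movement decision rules in mixed-species foraging flocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement decision rules in mixed-species foraging flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flockdecide` analyses collective movement decisions of individually marked
birds foraging at a patch of identical feeders monitored with RFID antennae.
This vignette explains the models the package implements, the conventions it
adopts where the underlying procedures admit more than one reading, and what
its synthetic data can and cannot establish about real field data.

## The setting and the data

A *patch* is a set of `n_feeders` identical feeders (four by default) close
enough together that birds treat them as one foraging site but far enough
apart (tens of metres) that feeder choice is a real decision. Each feeder
logs one record per PIT-tagged bird per 15 s interval. A detection stream is
therefore a table `patch_id, timestamp_s, feeder_id, tag_id, species`, and
everything downstream is derived from it.

Within-patch *movement events* are pairs of consecutive detections of the
same bird at different feeders separated by at most a residency gap
threshold (default 240 s; longer gaps are treated as the bird having left
the patch between visits). For each event the package records the occupancy
of every feeder over the 30 s window before departure and before arrival —
counting distinct birds, split into conspecifics and heterospecifics
relative to the moving (focal) bird, with the focal itself removed — and the
relative densities `rho` (per-feeder count divided by the patch total).

Three conventions here are choices of this package, documented because the
procedure admits alternatives:

* **Windows are half-open**, `[t - 30, t)`: the departure/arrival interval
  itself is excluded. "Prior to" does not fix inclusivity; the half-open
  form avoids letting the arrival detection count toward its own context.
* **A bird logged at two feeders within one 15 s interval** (a fast flight)
  yields an event with a zero gap; the lower-numbered feeder record is
  treated as the origin. Such ties are rare and the tie-break is
  deterministic.
* **Events whose window holds no other bird** (patch total zero after focal
  removal) keep undefined (`NA`) densities and are excluded from the curve
  and likelihood stages rather than being coerced to zero.

The 240 s default threshold can be re-derived from data with
`estimate_gap_threshold()`, which fits a two-component exponential mixture
to inter-detection gaps by EM (deterministic moment-based initialization)
and reports the gap at which the component responsibilities cross 0.5 — the
point where the gap distribution turns from the within-visit peak into the
between-visit tail. It is a heuristic stand-in for eyeballing the
distribution's inflection; with fewer than 50 gaps it refuses and recommends
the 240 s default.

## Density-conditioned movement curves

How does the probability of leaving or arriving at a feeder depend on the
fraction of the flock already there? With `P(A) = 1/4` as the prior
probability that a given feeder receives an arrival (all feeders are
identical), Bayes' rule gives

$$P(A \mid \rho) = \frac{P(\rho \mid A)\, P(A)}{P(\rho)},$$

where `P(rho)` is the frequency of densities observed on all feeders across
all event windows and `P(rho | A)` the frequency at arrival feeders; the
leaving curve uses origin feeders in the same way. `empirical_density_curves()`
evaluates this bin-wise on eleven equal-width bins centred on 0.0–1.0.
Whether `P(rho)` pools departure- and arrival-window densities or keeps them
separate is an open choice; pooled is the default and both are exposed.

Uncertainty is summarized two ways: a delta-method Monte Carlo standard
error per bin, and the delete-d jackknife of `jackknife_envelope()` — the
min–max range over 1000 re-estimates with 40% of events removed. Being
ratio estimates, the curves can exceed 1 under sampling noise and bins never
observed in `P(rho)` are undefined (`NA`), not zero. The curve also reports
the *realized mean density* per bin; analytic references should be evaluated
there, because with 0.1-wide bins the gap between the bin midpoint and the
density the bin actually represents can reach ~0.04 — discretization, not
estimator error.

### The asocial null (TASP)

The theoretical asocial prediction describes a flock with no social
attraction: a uniformly chosen mover sits at a feeder with probability equal
to its density, so `P(L | rho) = rho` — in particular a feeder holding the
entire patch is left with probability 1 — and it relocates uniformly among
the other three feeders, so `P(A | rho) = (1 - rho)/3`, which is decreasing
in density and sums to 1 over the four feeders of any configuration. An
increasing variant proportional to `0.33 rho` is retained behind the
`literal` switch of `tasp_curves()` for comparison, but the decreasing form
is the one consistent with inverse-density relocation and probability
conservation, and it is the default everywhere.

## The decision model

The social decision rule scores each feeder `x` by

$$P(X_x \mid B) = \frac{1}{1 + a\, s^{-\left(n_x - k \sum_{i \neq x} n_i\right)}},$$

with the two-rate variant splitting the exponent into conspecific and
heterospecific terms with rates `s_c` and `s_h`. The parameters:

* `s` — the rate of social information use: how much more often another bird
  is judged to make a good choice than a bad one. `s = 1` is the asocial
  limit: after probability matching, every feeder is chosen with probability
  exactly 0.25, whatever the occupancy. Large `s` makes the response
  sigmoidal (a strong threshold).
* `k` — how much occupancy elsewhere discounts a feeder (relative vs
  absolute comparison). `k = 0` is allowed and often selected; the fitted
  lower CI frequently sits at this bound.
* `a` — nonsocial information quality; `a > 1` penalizes empty feeders.

Because the raw scores need not sum to 1, a probability-matching step
divides each score by their sum. Consequences worth noting: the probability
of choosing an empty feeder is never exactly 0; equal occupancies give
exactly 0.25 each by symmetry; and setting `s_c = s_h` collapses the
two-rate variant to the single rate exactly. Scores are computed in log
space (`plogis` of the exponent on the log scale), so extreme rates and
counts saturate gracefully instead of overflowing. Exponents use raw counts,
not proportions: densities `rho` appear only in the empirical curves.

`choice_surface()` maps the choice probability over all combinations of
conspecifics and heterospecifics at a focal feeder for fixed patch totals,
with birds not at the focal feeder split as evenly as integer counts allow
across the others (remainders to the lowest-numbered feeders — the
convention is recorded in every surface object). `threshold_count()` reads
off the smallest count at which a feeder is chosen more often than at random
(P = 0.25); with an attractive rule this threshold scales with the patch
total rather than staying constant.

## Likelihood and fitting

Each movement event is scored by the probability of the observed arrival
feeder. Two conventions are first-class:

* **conditional** (default): the choice probabilities are renormalized over
  the three non-origin feeders — conditioning on the fact that a move was
  observed. Under `s = 1` every event then has probability exactly 1/3.
* **unconditional**: the arrival feeder is scored against all four feeders,
  i.e. including "stay".

The occupancy context is the arrival window by default (the information
available when the destination is chosen), with the departure window as an
option. The conditional/arrival pair is the package default because data
consisting only of observed moves carry no information about stays: fitting
the stay-included convention to movement-only data is a sensitivity
analysis, not an interchangeable estimator, and the test suite demonstrates
that the two conventions disagree on identical data. Every serialized fit
records which convention produced it.

`fit_decision_model()` maximizes the summed log-likelihood over
`log s` (or `log s_c`, `log s_h`), `log a` and raw `k`, with box bounds
(log scale in [-3, 6], `k` in [0, 5]) via `L-BFGS-B`, retrying from five
dispersed starts if the primary start fails. The `s = 1` null log-likelihood
is reported with every fit; since the null is nested, the fitted value can
never fall below it. `profile_ci()` computes 95% profile-likelihood
intervals: the set of parameter values whose re-optimized log-likelihood
lies within `qchisq(0.95, 1)/2 = 1.92` of the maximum, endpoints by
expanding steps plus bisection, clipped at the bounds with a boundary flag
(the `k >= 0` bound is the common case).

## Synthetic data: what it emulates, and the defaults

No field data ship with the package; `generate_dataset()` produces detection
streams with the structural features that matter for the method:

* **Community**: five species with strongly skewed abundances — blue tit,
  great tit, marsh tit, coal tit, nuthatch — with a default tagged pool of
  825/813/133/101/32 birds and activity weights of roughly 34/33/16/11/6%
  (renormalized to sum to one). The skew is what makes conspecific and
  heterospecific attraction genuinely different quantities for different
  species.
* **Bursty visits**: flock arrivals follow a homogeneous Poisson process
  (default 6 visits/h) and flock sizes a negative binomial (mean 25,
  dispersion 5, truncated at 2) — overdispersed groups of a few to several
  tens of birds, consistent with winter parid flocks in which the commonest
  species contributes a mean group of around ten. Neither law is dictated by
  the method; both are configuration entries, and the defaults are stand-ins
  chosen once on field-realism grounds.
* **Clumping**: a fresh flock is allocated across feeders by a
  Dirichlet-multinomial draw with concentration 0.5 per feeder, giving the
  strongly aggregated configurations (including near-empty and near-full
  feeders) that spread density across the whole [0, 1] range. Uniform
  allocation would concentrate all densities near 0.25 and starve both the
  curves and the likelihood of contrast.
* **Within-visit dynamics**: each present bird re-evaluates its feeder each
  interval with probability 0.1, choosing among all feeders (staying
  included) with the configured decision rule applied to focal-removed
  counts, and leaves the patch with per-interval hazard 0.025 (mean visit
  ≈ 10 min). Detection is complete: one record per present bird per
  interval; tag coverage and read failures are not modelled.

The generator's purpose is the closed loop: rules in, streams out, events
extracted, rules re-estimated. What passing recovery tests establish is that
the estimator is consistent and well-calibrated *under this generative
structure* — they cannot establish that real birds follow the model, nor
calibrate habitat, dominance, depletion or detection artefacts, none of
which are modelled.

`simulate_decisions()` is the decision-level generator used for parameter
recovery: each decision draws a fresh flock (focal bird plus flockmates,
conspecific split binomial from the species weights, feeders allocated with
the shared clumping draw) and samples the destination from the rule,
renormalized over non-origin feeders to match the conditional likelihood.
The recovery experiments at the package's reference sample size (2259
decisions, 20 replicates) are run by `scripts/acceptance.R` and the
acceptance tests.

## Agent-based replay and one deliberate asymmetry

`simulate_flocks()` replays a (fitted) rule: each of 1000 flocks starts from
a snapshot — drawn from a detection stream's occupied intervals or from the
parametric flock model — and runs 50 decision steps in which one uniformly
chosen bird stays or moves according to its species' rule (focal-removed
counts). Moves are emitted as movement events analysed by exactly the same
curve code as extracted data. Flock membership is fixed within a run; there
are no simultaneous movers.

One convention differs deliberately from extraction: simulation events
record the *complete pre-move configuration*, with the mover counted at its
origin feeder. With the mover's own presence subtracted from the emitted
densities, the Bayes-rule estimator applied to an asocial replay is not
consistent with the analytic null — the origin count is decremented while
the mover was selected in proportion to the undecremented count, and in
small flocks the distortion is large (a bird alone at a feeder has density 0
yet leaves it with positive probability). With the complete-configuration
convention the estimator reproduces `P(L|rho) = rho` and
`P(A|rho) = (1-rho)/3` exactly, configuration by configuration, which is the
property the asocial validation checks. Field extraction keeps full focal
removal (that is what the worked toy example defines); when comparing
extracted curves against simulated ones, the residual self-exclusion
distortion of order 1/(flock size) in the field curves is a known
limitation of the comparison, not of either estimator.

## Numerical choices

* Scores via `plogis` on the log scale; likelihood penalizes non-finite
  values with a large finite constant so box-constrained BFGS never sees
  `Inf`.
* Optimizer bounds `log s, log a` in [-3, 6] and `k` in [0, 5] cover the
  plausible magnitudes by a wide margin while keeping profiles searchable.
* Profile endpoints: expanding steps (factor 1.6) then 40 bisection
  iterations to 1e-3 on the transformed scale.
* The EM mixture fit for gap thresholds is deterministic (moment
  initialization, fast component kept first, relative log-likelihood
  tolerance 1e-8) and rounds its crossing to logging-interval resolution.
* All stochastic entry points take an explicit seed and restore the RNG
  state afterwards (`withr`); the pipeline derives per-stage seeds from its
  master seed by fixed offsets.

## Scale of the shipped checks

The test suite and acceptance script size their simulations to run in
minutes: the asocial-replay validation uses the full 1000 flocks × 50
decisions; parameter recovery uses the reference 2259 decisions × 20
replicates per species; profile-coverage checks use 50 replicates of 300
decisions (wider intervals, same calibration question). These sizes are the
package's chosen reference conditions and are stated here so that users who
scale them up know what the shipped numbers mean.

## Known limitations

* No spatial geometry beyond feeder identity; no depletion, dominance or
  predation dynamics; no between-patch movement.
* Detection is treated as complete; untagged birds and read failures are
  absent from both the generator and the estimators.
* Individual- or dyad-level rates are out of scope: rates are fitted per
  species (or pooled).
* The stay-included likelihood convention is unidentifiable from
  movement-only data and is provided for sensitivity analysis only.
* Empirical curve values are ratio estimates: they can exceed 1 and are
  undefined in never-observed bins; bins with fewer than 5 events are
  flagged `low_n` and no smoothing is applied.
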