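---
title: "Measuring cognition from error-correcting responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognition from error-correcting responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(changeofmind)
```

## The measurement problem

Conflict-based cognitive tasks estimate interference control, response
inhibition and response-rule switching from reaction-time differences
between regular and conflict trials. In most tasks a trial ends at the
first response, so the common human tendency to *change one's mind* — to
reverse a mistaken initial response within the same trial — is invisible.
A tunnel-running game in which players steer a group of rats through
colour-matched obstacle sections keeps the trial alive after the first
response: players can reverse a wrong rotation (an error-correcting
response in regular, mismatching-flanker and rule-reversed "ice" trials)
or release an ongoing movement after a lava stop-signal. This package
provides, in one place,

* a generative simulator for such sessions (`simulate_session()`,
  `simulate_cohort()`), so that every downstream method can be validated
  against known ground truth;
* the data-quality rules the measurement design prescribes
  (`score_player_exclusions()`, `filter_trials()`,
  `measure_eligibility()`);
* the measures: RT1 (time to a correct first response), RT2 (time from
  the colour assignment to the initiation of a reversal), time-to-stop
  (TTS, stop-signal onset to the release of an ongoing response that is
  followed by a corrective response), and integration-method SSRT
  (`extract_response_table()`, `extract_tts_table()`,
  `ssrt_integration()`);
* the hierarchical measurement models (`conflict_model()`) with CR2
  cluster-robust inference (`cr2_inference()`), per-player effects
  (`player_effects()`) and the precision ratio (`precision_eta()`);
* reliability machinery: even-odd split-half with Spearman–Brown
  correction, McDonald's omega for z-composites, BCa cluster bootstrap
  and a nested-bootstrap validity simulation.

The scientific question the toolchain addresses is *cognitive
continuity*: do error-correcting responses express the same latent
processes as correct initial responses, so that they can supplement (or
replace) them in conflict-based measurement?

## The generative model

### Choice trials

A first response on a non-lava trial arises from a three-way mixture:

1. **Fast guess** (probability `guess_base`, per player). An impulsive
   response with 50/50 accuracy whose latency (~60 ms before the
   non-decision time) does not depend on the conflict condition.
2. **Conflict capture** (probability `flanker_capture` and/or
   `ice_capture` on conflict trials). The conflict-implied incorrect
   response is emitted with the same impulse-like latency — the classic
   fast-error signature of flanker tasks.
3. **Deliberate decision.** A drift-diffusion accumulator (drift
   `drift_base` evidence/ms, symmetric boundaries `±boundary`, unit
   diffusion coefficient, Euler–Maruyama with 1 ms steps, uniform
   starting-point variability of `start_var × boundary`) starts after a
   per-player *conflict-resolution delay* (`flanker_misdirection`,
   `ice_misdirection`, in ms) on conflict trials. The first boundary
   crossing plus the non-decision time gives the first response.

The delay, not a drift decrement, carries the individual differences in
conflict effects: in this regime drift decrements move accuracy far more
than they move correct-response times, and the delay is the only
mechanism that produces conflict effects of several tens of milliseconds
at realistic accuracy. A small drift decrement per condition remains as a
secondary knob.

After any incorrect first response the *same* accumulator — with
probability `correction_engage`, and after a post-error reconsideration
lag (~150 ms) — continues from the incorrect boundary toward the correct
one with drift `post_gain × drift_base` minus the post-decision
decrements (`flanker_decrement_post`, `ice_modifier_post`). Reaching the
correct boundary initiates the error-correcting response; RT2 is clocked
from the colour assignment, like all event times. A trial succeeds when
the correct boundary is reached inside the response window. Players who
have not decided as the obstacle arrives usually emit a forced deadline
guess; with probability `lapse` a trial is skipped entirely.

### Lava trials and the two staircases

On lava trials the go process above races an independent stop process
finishing at `ssd + N(stop_latency_mean, stop_latency_sd)`. If the stop
process wins there is no movement; otherwise the movement is released
when the player's release process finishes, and with probability
`lava_correction_prob` a corrective response follows (~191 ms later, the
game's observed average), making the trial TTS-eligible. The release
process shares each trial's stop noise but is centred on a second latent
mean whose correlation with the race latency is `stop_share`: at 1 the
latency measured by SSRT and the latency measured by TTS are the same
quantity.

Two adaptive mechanisms mirror the game. The stop-signal delay staircase
(per flanker condition, from 300 ms) moves the lava onset 50 ms earlier
after a response and 50 ms later after an inhibition, targeting a 50%
respond rate. The response window (from 1317 ms) shortens by 20 ms after
a success and lengthens by 80 ms after a failure; the 4:1 asymmetry fixes
the stationary success rate at 80% (the published design states the
target but not the step sizes; the 4:1 rule is the simplest staircase
with that stationary point, and the 20 ms magnitude is configurable).
The window staircase adapts on regular and mismatching-flanker outcomes
only, as in the game; ice trials therefore run slightly below the 80%
target and drag the pooled non-lava success rate a few points under it.

### The continuity knobs

`continuity_flanker` is the population correlation between a player's
pre-decision flanker interference (the resolution delay) and the
post-decision flanker decrement. At 1, the interference slowing a
player's corrections is the same latent quantity that slows their correct
first responses, so per-player flanker effects on RT1 and RT2 correlate
strongly; at 0 they share almost nothing — fast guesses and capture
errors were given conflict-independent latencies precisely so that the
first-response segment of RT2 carries (almost) no conflict information.
`continuity_ice` plays the same role for the rule-reversal effect; its
default is strongly negative with a small mean post-decision modifier,
the *discontinuous* regime in which the ice effect on corrections is
roughly half the size of the effect on first responses and the two do not
positively correlate. These defaults reproduce the qualitative pattern
the game's data show; setting `continuity_ice` positive produces the
continuous regime instead.

Default population values were chosen once to land near the published
descriptive statistics — roughly 190 analysed first responses and 30
error-corrections per player for the flanker contrast, about 30 TTS
observations per player, flanker effects of ~40 ms on RT1, ice effects
about twice the flanker effect with the RT2 ice effect halved, a ~20%
player exclusion rate — and are not re-tuned thereafter.

### What the generator does not emulate

Real sessions have sequential structure (post-error slowing, congruency
sequences), motor kinematics of the continuous rotation, fatigue and
block breaks, frame-rate jitter (fps is a per-player constant used only
by the exclusion rules), and trial-to-trial parameter drift. Passing
tests therefore show that the *methods* behave as intended on data with
the assumed structure, not that the game's real data satisfy that
structure.

## Measures

`extract_response_table()` emits one row per correct first response
(RT1), one per incorrect first response (kept for decomposition), and one
per error-correcting response (RT2), with the correction's delay since
the initial response for filtering. `extract_tts_table()` emits
`TTS = release_time − ssd` only when a corrective response follows the
release. `ssrt_integration()` implements the integration method: with
respond rate *p* over stop trials, non-responses in the condition-matched
go-RT set are replaced by the maximum observed RT, the RTs sorted
ascending, and SSRT is the RT at rank ⌈p·n⌉ minus the mean stop-signal
delay (*p* = 0 is an error; *p* = 1 computes the boundary rank with a
warning). Each flanker condition's SSRT uses its own condition-matched
go set (regular trials for the matching sub-measure, mismatching non-ice
trials for the mismatching one), mirroring the conditioning of the SSD
staircases. `composite_z_average()` builds the two- and three-indicator
z-composites with the n−1 SD convention over the analysed cohort.

## Data-quality rules

`score_player_exclusions()` awards two points for: mean frame rate below
35; first-response accuracy no higher than three binomial standard errors
(√(0.25/n)) from 0.5; non-response on more than 10% of non-lava trials.
One point for: lava stopping rate outside [0.3, 0.7]; correcting under
30% of opportunities in non-lava or in lava trials; non-response above
3%; frame rate below 45. Two points exclude. The accuracy rule is
one-sided by default (the rule targets near-chance responders and
above-chance play is the norm); a two-sided variant is a switch.
Opportunities to correct are trials with an incorrect first response
(non-lava) or a post-signal response (lava).

`filter_trials()` drops first responses outside [300, 1500] ms and
corrections arriving more than 1 s after the initial response (non-lava)
or the stop signal (lava), then applies a per-player, per-condition 3 SD
rule (conditions are the flanker-by-ice cells; lava corrections split by
flanker condition). The SD rule is iterated to a fixed point so that the
filter is idempotent; no trial-level filtering ever touches the SSRT
inputs. `measure_eligibility()` requires at least three retained
corrections per relevant trial type and, for SSRT/TTS, a stopping rate
inside [0.30, 0.70].

## Measurement models

`conflict_model()` fits REML linear mixed models with 0/1 treatment
indicators (reference: non-conflict trial, first response) and the player
as grouping factor:

* `maximal_joint` — fixed and random intercept, trial type, response type
  and their interaction; used to estimate per-player conflict effects
  separately per response type.
* `shared_conflict` — full fixed structure but no random interaction:
  conflict-effect individual differences are shared between response
  types. This is the measurement model that *combines* first responses
  and corrections under the continuity assumption.
* `single_response` — random intercept and trial-type slope, for one
  response type at a time.
* `tts_model` — random intercept, fixed trial type, for time-to-stop.

Non-convergence triggers one restart from perturbed variance parameters
and is otherwise flagged, never silently simplified; singular
(boundary) variance estimates are legal REML solutions and are not
treated as failures.

Fixed effects are tested with CR2 cluster-robust standard errors and
Satterthwaite degrees of freedom, written from first principles: per
cluster, the adjustment `A_j` is the symmetric matrix with
`A_j G_j A_j = V_j`, where `V_j` is the working (model-implied marginal)
covariance and `G_j = V_j − X_j M X_j'` its residual counterpart; the
degrees of freedom come from the trace ratio of the working-model
covariance of the per-cluster score contributions. With identity weights
and singleton clusters the estimator reduces exactly to HC2 — that
identity, checked against an independent heteroscedasticity-robust
implementation, and a type-I-error simulation are part of the test
suite.

`player_effects()` returns empirical-Bayes conditional modes by default.
For *correlating* effects across response types the package uses the
no-pooling per-player scores instead: with sparse correction data the
conditional modes shrink toward the fitted random-effect ellipse, which
inflates cross-response-type correlations (a bias visible under a
zero-continuity generator), and the published correlation tests with
df = n−2 imply plain per-player scores. Both estimators are available.

`precision_eta()` returns the ratio of the individual-differences SD of
a model component to the residual SD — the quantity that governs how
reliability scales with trial count (trial-type slope for conflict
effects, intercept for TTS).

## Reliability

`split_half_reliability()` splits trials by the within-condition parity
of the trial index, recomputes the measurement per half (refitting the
hierarchical model for model-based measures) and applies the
Spearman–Brown correction; raw and corrected values are both returned.
`mcdonalds_omega()` gives single-factor composite reliability
`(Σλ)²/((Σλ)²+Σθ)`: with three standardized indicators the model is
just-identified (`λ_i = √(r_ij r_ik / r_jk)`), with two an
equal-loadings constraint identifies `λ = √r` — the identification used
for the first-responses-only composite, since nothing in the published
analysis suggests otherwise. `bca_ci()` is a player-level (cluster)
bootstrap — reliability is a between-player statistic — with bias
correction from the bootstrap proportion below the point estimate and
acceleration from the jackknife over players; with `z0 = a = 0` it
reduces to the percentile interval, and defaults to B = 2000 (the
published analyses used 100,000; endpoints stabilise far earlier, and B
is configurable up to that).

`trial_equivalent_gain()` maps a reliability increment `r1 → r2` onto a
baseline of 0.50 through the Spearman–Brown effective-trial multiplier
`m = r2(1−r1)/(r1(1−r2))`. The originally cited trial-number formula is
not available to us in algebraic form, so the published mapped values are
treated as documentation rather than as an oracle; the implementation
guarantees the identity at `r1 = r2` and monotonicity.

`nested_bootstrap_validity_sim()` reproduces the methodological caveat
that motivated reporting *point* differences between nested
measurements' reliabilities without intervals: when measure B nests
measure A's trials, the player bootstrap misjudges the coupling between
the two reliabilities and hence the uncertainty of their difference. The
pipeline therefore never reports CIs for such differences.

## Numerical choices and edge cases

* Euler–Maruyama step 1 ms, unit diffusion coefficient; the step is a
  parameter for convergence checks (the analytic first-passage mean
  `(a/v)·tanh(av)` is verified at a fine step, where the residual
  deviation is the expected boundary-overshoot bias).
* The error-correcting response uses the opposite (correct) boundary of
  the same accumulator; the crossing value is reset to the boundary
  (overshoot ignored).
* Staircase values floor at 0; SSD staircases use equal 50 ms steps by
  definition.
* `ssrt_integration()` breaks rank ties by stable ascending sort.
* Degenerate inputs are explicit: zero-variance composites, zero stop
  rates, zero-variance paired differences and sub-4-cluster CR2 all
  signal rather than return silently.
* All randomness flows through seedable entry points; operations taking
  a `seed` are pure functions of their inputs and restore the caller's
  RNG state.

## Problem sizes used in the shipped checks

The package's own test suite validates the staircase targets on 100
simulated sessions, parameter recovery (a 50 ms conflict effect, a 30 ms
random-slope SD, a 0.5 precision ratio) on 100-player cohorts generated
from the Gaussian measurement model, stop-latency recovery and the
SSRT-truth correlation on the 100-session game cohort, continuity
discrimination on an 80-player cohort plus twenty 30-player
null-continuity replicates, reliability behaviour on twenty 45-player
cohorts, BCa coverage with 500 replicates at B = 2000, and CR2 type-I
error with 500 null fits. These sizes were chosen as the smallest that
leave the Monte Carlo error well inside each criterion's band.

## Known limitations

The generator's mixture structure is one of several that satisfy the
observed constraints; it makes incorrect initial responses *fast* under
conflict, whereas the game's data show a positive conflict effect on
incorrect-initial times — a deliberate trade-off, since a strong positive
carry-over of pre-decision conflict into RT2 is mathematically
incompatible with near-zero effect correlations under zero continuity.
Accuracy-based conflict scores, evidence-accumulation model *fitting*,
test–retest reliability and trial-sequence effects are out of scope.
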