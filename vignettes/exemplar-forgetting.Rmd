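---
title: "Exemplar forgetting, environmental recency, and what model fits can(not) diagnose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exemplar forgetting, environmental recency, and what model fits can(not) diagnose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recatmem)
```

## The problem

In category learning, prototype models store one ideal member per category
while exemplar models store every experienced instance. Learning curves and
model-fit comparisons are routinely used to infer which representation
people rely on, and shifts in relative fit over the course of an experiment
have been read as strategic shifts between representations — in particular
when the presentation schedule is manipulated: under uniform random
presentation the exemplar model's fit advantage grows over time, whereas
under a power-law schedule (recently seen items re-appear much more often)
the advantage starts large and shrinks.

`recatmem` implements the competing, more parsimonious account: a single
exemplar model whose traces decay as a power law of time can *generate* both
patterns under one fixed parameter set. The package provides everything
needed to make that argument computationally: the stimulus structure, the
two presentation schedules with recency diagnostics, the four classification
models, the two fitting objectives with their per-condition policies, a
Bernoulli response simulator, and the model-recovery analyses.

## Stimuli

The rule-plus-exception structure uses `M = 6` binary feature dimensions.
Category A's prototype is `000000`, category B's `111111`; each category has
five "typicals" at Hamming distance 1 from its own prototype and one
"exception" at distance 1 from the *opposite* prototype (so distance 5 from
its own). Rendered as nonsense words with the default letter table, the
prototypes read `gafuzi` and `livamo` and the category-A exception `livazo`.

```{r stimuli}
cs <- render_words(make_rule_plus_exception())
cs$stimuli[, c("id", "category", "role", "word")]
```

Which dimensions are flipped is deterministic, and one choice deserves
emphasis. The A exception flips dimension 5 of the B prototype (`111101`)
and the B exception flips dimension 6 of the A prototype (`000001`), while
typicals use every dimension *not* taken by the opposite category's
exception (A: 1–5, B: 1,2,3,4,6). A prototype model can classify an
exception "correctly" by loading attention onto its distinguishing
dimension (weight above 1/2), so if the exception dimensions were unused by
typicals this rescue would be free and the two model families would become
indistinguishable on fitted data. Under the chosen assignment every
exception shares its dimension with one of its own category's typicals:
rescuing the exception necessarily misclassifies that typical. This is the
structural fact behind the diagnostic claim that prototype models cannot
fit exceptions and non-exceptions at once, and the package's tests assert
both the claim (under attention weights below 1/2 on the exception
dimensions) and its sharpness (the trade-off when a weight exceeds 1/2).
With more than one exception per category the 6-dimensional structure
cannot avoid duplicate vectors and the constructor refuses; the exception
count is a knob for smaller or zero-exception designs, not for crowding.

## Presentation schedules

Both conditions run `T = 616` trials over the 14 stimuli.

**Control (uniform)**: every consecutive block of 14 trials is a random
permutation of all stimuli, for 44 blocks. Each stimulus appears exactly 44
times; the delay between repetitions averages 14 trials and is flat across
the experiment.

**Experimental (power-law)**: a new stimulus is introduced every 35 trials
(trials 1, 36, …, 456, randomized order). After its introduction a stimulus
re-appears on a power-law schedule: the gap before its k-th presentation
grows as `k^gamma` (default `gamma = 1`), jittered log-normally
(`jitter_sd = 0.25`) and scaled to the trials remaining after introduction,
with a per-stimulus quota of `616/14 = 44` presentations. The per-stimulus
schedules are interleaved greedily (each non-introduction trial shows the
introduced stimulus whose next scheduled re-presentation is earliest due).

The generator's design was genuinely open, and two simpler candidates were
rejected on their diagnostics. Competitive sampling with weight
`(delay since last seen)^-gamma` is quasi-stationary: the mean delay per
power-law segment fluctuates around a constant instead of growing, which
contradicts the defining property of the design. Sampling by stimulus age
produces the delay gradient but lets presentation counts drift far apart
across stimuli, so late power-law segments no longer contain trials
comparable to late control segments. The scheduled-gap design yields both
signatures at once: per-segment mean presentation counts identical to the
control condition, and delays that surge across late segments.

Two limits of any such generator are worth knowing. While only one or two
stimuli have been introduced, full occupancy forces them to repeat at delay
≈ 1, so the first few power-law segments tie at the floor rather than
increasing strictly; and the fixed trial budget compresses every stimulus's
final presentations into the closing trials, which caps the last segment's
mean delay. The package therefore documents and tests the delay profile as
non-decreasing through segment 10 with late segments several times the
early ones, on cohort averages (single sequences are noisy; the profile is
a cohort-level quantity).

**Segments.** Control trials are analysed in 11 contiguous 56-trial
("sequential") segments; any remainder under other configurations is
absorbed by the final segment. Experimental trials are binned by
presentation index ("power-law" segments, temporally discontiguous):
cut-points on the presentation index are chosen by greedy balancing of its
histogram so segments hold ≈ 56 trials on average while grouping trials at
similar points along each stimulus's re-presentation curve.

`recency_profile()` summarises a sequence: need odds
`P(stim)/(1 - P(stim))` by recency lag, and per-segment mean delay and mean
prior presentation count. First appearances have no defined delay and are
excluded from delay means (but stay in all model computations — the store
simply lacks that stimulus).

## Models

All four families share an attention-weighted city-block distance on the
binary features, `d = Σ_m w_m |x_m − y_m|`, with `w` on the simplex, and an
exponential similarity `s = exp(−c d)`.

* **Prototype**: distances to the two fixed true prototypes;
  `P(A) = s_A / (s_A + s_B)`. Six free parameters (five weights + `c`).
* **Exemplar**: summed similarity to every stored token, by category;
  `P(A) = Σ_A s / (Σ_A s + Σ_B s)`. Six free parameters.
* **Exemplar-forgetting**: each token's similarity is multiplied by its
  memory strength `M_j = j^{−β}`, `j` the delay in trials since storage.
  Seven free parameters. `β = 0` reduces exactly to the exemplar model.
* **Mixture**: `α·P_prototype + (1 − α)·P_exemplar` with a shared weight
  simplex and separate sensitivities — eight free parameters with scalar
  `α`; `α` may instead vary by segment.

Token bookkeeping follows four conventions. One token is stored per past
trial (repetitions accumulate — exemplar predictions are sensitive to the
total number of tokens seen). Tokens carry the feedback (true) category,
since feedback is always given. The current trial's stimulus is excluded
from its own prediction's store, so recency is well defined. An empty store
(trial 1) yields `P(A) = 0.5`, and a one-sided store simply contributes a
zero sum for the absent category. Delays are measured in trials. No
response-scaling exponent is included: predictions are the γ = 1 case, and
keeping the parameter counts at 6/6/7 makes the forgetting comparison
clean.

`predict_sequence()` runs any family along a sequence; a compiled kernel
accumulates the token sums, and the tests verify it against a naive R
store-rebuilding loop to 1e−12. Per-segment parameter vectors (the
simulation's sensitivity schedule, the mixture's per-segment `α`) are
resolved through a segment assignment.

## Fitting

Two objectives are implemented, matching how such data are analysed:

* `sse_segment`: for each stimulus present in a segment, compare the
  observed proportion of category-A responses with the model's predicted
  proportion, and sum the squared differences. For history-dependent models
  the predicted proportion is the mean of the per-trial predictions within
  the segment — the only definition that exists when predictions vary
  across a segment. Stimuli absent from a segment contribute no term.
* `mse_trials`: mean squared error between per-trial predictions and 0/1
  responses. Unlike the aggregated objective this is sensitive to
  trial-level recency structure, which is precisely what a forgetting
  mechanism predicts.

The per-condition policy mirrors the source analyses: control-condition
aggregated fits are per participant × sequential segment; control
trial-level fits and all experimental fits are per participant over all
trials simultaneously, with only the mixture's `α` varying across
power-law segments in the experimental condition.

The optimizer is bound-constrained quasi-Newton (L-BFGS-B) with the weight
simplex handled by a softmax reparameterisation (five free logits, the
sixth fixed at 0, bounds ±16), `c ∈ [0, 30]`, `β ∈ [0, 5]`, `α ∈ [0, 1]`.
The bounds comfortably contain the simulation protocol's values (`c` up to
10.5, `β = 0.7`). Each fit runs from a fixed equal-weight start plus seeded
random starts (weights from a flat Dirichlet; scalars uniform), and callers
can append *nested starts* — the optimum of a restricted model mapped into
the larger family (exemplar → forgetting at `β = 0`; components → mixture
at `α ∈ {0, 1}`). With nested starts the textbook monotonicity (a freer
model never fits worse) holds up to optimizer tolerance, and the tests
assert it. If every start fails, the best evaluated point is returned
flagged as non-converged rather than raising. `β` can be held fixed
(`beta_fixed`) to reproduce analyses that pin the forgetting rate.

## The synthetic-data generator

`simulate_cohort()` is the package's study-data stand-in. Its defaults are
the demonstration protocol: equal attention weights of 1/6, sensitivity
rising from 5.5 to 10.5 in steps of 0.5 across the 11 segments (sequential
segments in control, power-law segments in experimental — the same schedule
in both conditions), forgetting rate `β = 0.7`, 30 participants per
condition, independent presentation sequences per participant (a
`shared_sequence` flag covers the fixed-schedule alternative), and
Bernoulli-sampled responses from the per-trial `P(A)`. The rising
sensitivity emulates learning; the fixed `β` embodies the claim under test
— a *constant* forgetting process in both conditions.

What the generator does not emulate: individual parameter differences,
attention drift, lapses, reaction times, or any strategic adaptation.
Passing recovery tests on these cohorts therefore shows that the analysis
pipeline draws the right conclusions *when the forgetting account is true
and participants are exchangeable* — it does not show that real
participants forget this way, and fits to real data may be noisier in ways
this generator cannot produce.

## Trend statistics and analysis choices

Trend claims ("the exemplar advantage grows over control segments",
"shrinks over experimental segments") are operationalized as the
prototype-minus-exemplar fit gap's first-versus-last-segment difference
together with its Spearman rank correlation over segments; the recovery
report exposes both, and the qualitative flags use the first-vs-last
difference. Error bars everywhere are standard errors of the mean across
participants, not trials. Experimental-condition fit curves are the
per-power-law-segment MSE of the whole-experiment fit (the plotting
convention for that condition). The fit partition by item type splits the
aggregated objective exactly (exception + non-exception = total) and the
trial-level objective as a trial-count-weighted mean; with two exceptions
and twelve non-exceptions, a model fitting every stimulus equally well
shows an exception share of one-sixth.

The post-introduction restriction keeps trials strictly after the first
trial at which every stimulus has appeared — from trial 457 in the default
experimental design and trial 15 in the control condition — so that
retained trials are those whose store already contains every stimulus.

The mixture's `α` is unidentifiable when the two component predictions
coincide (e.g. both sensitivities at 0); the comparison routine flags
participants whose fitted components are numerically indistinguishable
instead of reporting a meaningless `α`.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full design (616 trials,
14 stimuli, 11 segments) with cohorts of 30 simulated participants for
accuracy and model-recovery trends (three seeds for stability) and 10
participants for the forgetting-rate recovery, using 2–3 optimizer starts
plus nested starts with iteration caps of 60–100; these sizes give stable
qualitative trends while keeping a full run in the minutes range on one
core. The forgetting-rate recovery deliberately fits a *single* sensitivity
to data generated with a rising per-segment schedule, so the estimate of
`β` carries a model-misspecification bias; the acceptance suite measures
the recovered mean against calibration runs rather than asserting exact
equality. Reproducibility conventions: every stochastic routine takes a
seed and restores the caller's RNG state; participant- and restart-level
seeds are derived deterministically from the master seed; regenerating any
object with the same arguments is bit-identical.

## Limitations

* The power-law generator is a principled reconstruction of the design's
  *statistics* (introduction schedule, equal exposure, delay growth), not a
  bit-level replica of any particular experiment's sequences.
* Only binary features and two categories are supported; there is no
  likelihood-based or hierarchical estimation, and no information-criterion
  model comparison — raw SSE/MSE only, as in the analyses this package
  reproduces.
* Aggregated (`sse_segment`) fits on 4-observation proportions are noisy;
  per-segment fit curves need cohort averaging to be interpretable, and
  endpoint-based trend statistics inherit that noise (hence the Spearman
  statistic is reported alongside).
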