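# recatmem

Category-learning experiments diagnose memory representations by comparing
two model families: **prototype models**, which classify a stimulus by its
similarity to one ideal member per category, and **exemplar models**, which
classify by summed similarity to every stored instance. When the
presentation schedule is manipulated — uniform random presentation versus a
power-law schedule in which recently seen items re-appear far more often —
learning curves and model-fit comparisons move in opposite directions
across the two conditions, a pattern that has been interpreted as a
strategic shift between representations. `recatmem` implements the more
parsimonious alternative: a single exemplar model whose traces decay as a
power law of time reproduces both patterns under one fixed parameter set,
so the opposing trends diagnose the *schedule*, not a change of
representation.

The package is aimed at computational cognitive modellers who want to
simulate, fit, and stress-test these arguments end to end.

## The models

All families share an attention-weighted city-block distance over `M = 6`
binary features, `d_ij = Σ_m w_m |x_im − x_jm|` (weights on the simplex),
and exponential similarity `s_ij = exp(−c d_ij)` with sensitivity `c ≥ 0`:

* prototype: `P(A|i) = s_iA / (s_iA + s_iB)` against the fixed prototypes
  `000000` and `111111` (6 free parameters);
* exemplar: `P(A|i) = Σ_{j∈A} s_ij / (Σ_{j∈A} s_ij + Σ_{j∈B} s_ij)` over
  one stored token per past trial (6 parameters);
* exemplar-forgetting: each token weighted by its memory strength
  `M_j = j^{−β}`, `j` the delay in trials since storage (7 parameters);
* mixture: `α·P_prototype + (1−α)·P_exemplar`, shared weights, separate
  sensitivities (8 parameters with scalar `α`).

Fitting minimises either the aggregated per-stimulus sum-squared error
within a segment (SSE) or the trial-level mean squared error (MSE) under
simplex and box constraints, from multiple seeded starts with optional
nested starts from restricted models.

## Worked example

```r
library(recatmem)

cs <- render_words(make_rule_plus_exception())
cs$stimuli[cs$stimuli$role != "typical", c("category", "role", "word")]
#>    category      role   word
#> 1         A prototype gafuzi
#> 7         A exception livazo
#> 8         B prototype livamo
#> 14        B exception gafuzo

# a 616-trial power-law sequence: introductions every 35 trials, then
# re-presentations that start frequent and grow rare
sq <- make_powerlaw_sequence(cs, seed = 5)
rp <- recency_profile(sq, assign_segments(sq, "power_law", 11))
round(rp$by_segment$mean_delay, 1)
#>  [1]  1.0  1.0  1.0  1.0  1.0  1.2  1.9  5.7 28.6 36.0 17.1

# simulate a cohort from the exemplar-forgetting model (equal weights,
# sensitivity 5.5 -> 10.5 across segments, beta = 0.7) and summarise
co <- simulate_cohort(simulation_protocol(n_participants = 8, seed = 31),
                      make_rule_plus_exception())
acc <- accuracy_by_segment(co, "control", split_exceptions = FALSE)
round(acc$mean_accuracy, 3)
#>  [1] 0.748 0.786 0.817 0.875 0.884 0.877 0.888 0.906 0.908 0.915 0.933
acc_e <- accuracy_by_segment(co, "experimental", split_exceptions = FALSE)
round(acc_e$mean_accuracy, 3)
#>  [1] 0.810 0.897 0.955 0.946 0.978 0.980 0.982 0.969 0.958 0.895 0.933
```

The same generating process yields monotone improvement under uniform
presentation (control) and a rise-then-fall under the power-law schedule
(experimental): repetitions drive learning in both conditions, but in the
experimental condition the delay since an item was last seen grows across
segments, and power-law forgetting eventually overwhelms the gains.
`model_recovery()` completes the argument: fitting the *base* prototype and
exemplar models to such cohorts reproduces the growing exemplar-fit
advantage in control and the shrinking advantage in experimental — without
any representational shift in the generator.

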