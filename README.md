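# choicetrace

Millisecond-resolved "choice traces" from trial-locked MEG source signals in a
context-dependent perceptual decision task.

## The problem

In a dual-stimulus random-dot task, each trial shows an adaptation stimulus
(AS) carrying one strong feature (70% colour dominance or motion coherence),
then a test stimulus (TS) judged on an instructed context — colour or motion —
at 12.8% or 25.6% strength. Repeating a feature between AS and TS suppresses
the neural subpopulation tuned to it (repetition suppression), so the
*difference* in the bulk MEG signal between repeat and non-repeat trials is a
time-resolved readout of when that feature is processed. Coding the
suppression conditions as regressors and fitting them to every time window
turns a single virtual sensor into a state-space-like trajectory from sensory
input to motor response: the choice trace.

`choicetrace` implements the full analysis stack for this design, plus a
synthetic generator with known ground truth so every stage has a
parameter-recovery test:

- **Task design** — balanced 64-condition schedules
  (4 AS types x 2 contexts x 2 directions x 2 colours x 2 coherences), the
  fixed response mapping (green/left -> index, red/right -> middle), the
  six-regressor repetition-suppression design (context, switch, relevant input
  adaptation, irrelevant input adaptation, response adaptation, choice), the
  four-regressor encoding design with signed input strengths in {-2,-1,+1,+2},
  and design-correlation checks (signed shared variance `sign(r) r^2`).
- **Synthetic data** — trial-locked source epochs as a sum of regressor-locked
  temporal kernels plus AR(1) noise, multi-parcel variants, per-session sign
  flips, and behavioural outcomes (logistic choices, log-normal RTs).
- **Sliding-window ridge GLM** — 150 ms windows stepped by 33.3 ms, ten 90%
  trial subsamples per window, penalty tuned per subsample on the grid
  `{1e-5, 1e-3, 1e-1, 1e1, 1e3, 1e5}` by inner 3-fold cross-validation,
  absolute coefficients (source polarity is arbitrary), ERP-correlation sign
  alignment across sessions, and permutation inference by re-running the whole
  estimator under row-shuffled designs (which preserves the design's
  covariance structure exactly).
- **Timing statistics** — leave-one-subject-out peak latencies (subject peaks
  constrained to ±66.7 ms around the other subjects' group peak),
  repeated-measures ANOVA with partial eta squared, paired t with Hedges'
  g (`g = mean(d)/sd(d) * (1 - 3/(4 df - 1))`) and bootstrap CIs, and choice
  traces plotting `|beta_input|` against `|beta_response|` over time.
- **Behaviour** — per-subject log-RT and logistic accuracy regressions on the
  six regressors with group-level tests, the context x training x coherence
  ANOVA, and psychometric curves in signed relevant/irrelevant evidence.
- **Decoding** — choice direction residualized out of every parcel, then
  nested cross-validated ridge decoding (10-fold outer, 3-fold inner) of
  relevant and irrelevant input strength per context, windows of 150 ms
  stepped by 63.3 ms.

Everything takes and returns tibbles, so stages chain with the pipe; results
have `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

```r
library(choicetrace)

# one synthetic subject: balanced schedule, behaviour, epochs
trials <- generate_session_schedule(2, 128, seed = 1) |>
  simulate_behaviour(seed = 2)
design <- code_rs_regressors(trials)
epochs <- simulate_source_epochs(design, seed = 3)

# design sanity: signed shared variance of the coupled regressor pairs
dc <- design_correlations(design)
subset(dc, var1 == "switch" & var2 == "rel_adapt")$signed_r2
#> [1] -0.3333333

# sliding-window ridge GLM on correct trials
keep <- trials$ts_correct == 1
epochs$data <- epochs$data[keep, ]
series <- fit_subsampled_glm(
  epochs, design[keep, ],
  grid = build_window_grid(250, 750), config = ridge_config(seed = 4)
)
dplyr::slice_max(dplyr::group_by(series, regressor), coef, n = 1)
#> # A tibble: 6 x 3
#>   window_center_ms regressor    coef
#>              <dbl> <chr>       <dbl>
#> 1             517. choice      0.771
#> 2             350  context     1.09
#> 3             383. irrel_adapt 0.515
#> 4             417. rel_adapt   0.901
#> 5             550  resp_adapt  1.09
#> 6             250  switch      0.977
```

The absolute coefficients peak where the generator placed them: the relevant
input representation at ~417 ms (injected peak 429.5 ms) with roughly twice
the irrelevant amplitude, the response representation at ~550 ms (injected
531.1 ms) — the input-before-response ordering the choice trace visualises
(`autoplot(build_choice_trace(series))`).

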