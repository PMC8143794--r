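---
title: "Recovering choice traces with repetition suppression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering choice traces with repetition suppression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicetrace)
```

## The experimental logic

A bulk MEG signal from one source location mixes many neural subpopulations.
Repetition suppression provides a handle on them: an adaptation stimulus (AS)
carrying one strong feature attenuates the neurons tuned to that feature, so
when a test stimulus (TS) repeats the feature, the measured signal is reduced
relative to trials where it does not. Coding repeat/non-repeat as 0/1
regressors and regressing the signal on them in sliding time windows yields,
for each feature, a time course of when that feature is represented — without
any multivariate decoding across sensors.

The task crosses 4 AS types (green, red, left, right at 70% strength) with
2 TS contexts (colour or motion relevant), 2 directions, 2 colours and
2 coherence levels (12.8%, 25.6%): 64 conditions, balanced within a session.
The response mapping is fixed throughout: green colour and leftward motion map
to the index finger, red and rightward to the middle finger. Six regressors
code each trial:

| regressor     | meaning                                                    |
|---------------|------------------------------------------------------------|
| `context`     | motion (1) vs colour (0) instruction for the TS            |
| `switch`      | AS stimulus dimension differs from the TS context          |
| `rel_adapt`   | AS feature repeats the TS feature on the attended dimension |
| `irrel_adapt` | AS feature repeats the TS feature on the unattended dimension |
| `resp_adapt`  | the finger required by the AS equals the correct TS response |
| `choice`      | right-pole (middle finger) response                        |

The coding has structural dependencies — `rel_adapt` implies no switch,
`irrel_adapt` implies a switch, `rel_adapt` implies `resp_adapt` — which put
the signed shared variance `sign(r)·r²` at exactly −1/3, +1/3 and +1/3 for the
three coupled pairs on a balanced schedule, and below 0.4 everywhere. A
separate encoding design codes TS properties only (context, signed relevant
and irrelevant input strength in {−2, −1, +1, +2} with the right choice as the
positive pole, and choice); on an all-correct balanced schedule the
relevant-strength/choice correlation is 3/√10 ≈ 0.949 by construction, which
is why decoding analyses residualize choice before estimating input coding.

One coding ambiguity is worth stating. "Switch" is defined here as the AS
*stimulus dimension* differing from the TS *instruction context*; since the AS
cue always matches the AS dimension, this is equivalent to a cue change. The
colour sign convention for input strength follows the response mapping (red ↔
middle ↔ right pole).

## The synthetic generator

`simulate_source_epochs()` builds each trial's trace as

$$x_i(t) = \Big(\sum_k X_{ik}\, \kappa_k(t)\Big)\,(1 + g_i) + \varepsilon_i(t),$$

where $X$ is the design matrix, $\kappa_k$ a temporal kernel per regressor,
$g_i \sim N(0, \sigma_g^2)$ a per-trial gain, and $\varepsilon$ AR(1) noise
with marginal SD $\sigma$ and lag-1 autocorrelation $\phi$. Kernels are the
package's own choice (the study reports onsets and peaks, not shapes):
sustained effects (context, switch) rise as a half-Gaussian from their onset
and hold to the end of the epoch; transient effects are Gaussian bumps
parameterised by peak and FWHM. Defaults follow the reported chronology —
context and switch from 8 ms; input adaptation onset 108 ms, peak 429.5 ms;
response adaptation and choice onset 275 ms, peak 531.1 ms — with amplitudes
of order one and the relevant input twice the irrelevant input (1.0 vs 0.5).
The post-training variant shifts transient peaks 75 ms earlier with unchanged
amplitudes, reflecting faster processing after over-training rather than
stronger coding. Effects enter with positive sign only: downstream analysis
uses absolute coefficients because source polarity is arbitrary, so the sign
is unidentifiable anyway.

Noise defaults — $\phi = 0.7$, $\sigma = 1$, $\sigma_g = 0.1$, and a 0.2 SD
multiplicative per-subject amplitude factor — are a plausible stand-in for
source-level MEG noise at 300 Hz, not an empirical fit; the source noise
spectrum is not characterised by the study, so AR(1)+white is exposed in
`noise_spec()` rather than hard-coded. The generator emulates additive,
regressor-locked effects, session sign flips and behavioural couplings. It
does not emulate realistic spectral content, artifacts, non-linear mixing, or
spatial leakage between parcels — so passing recovery tests demonstrate that
the estimator recovers what the linear model assumes, not that real data meet
those assumptions.

Behaviour: choices are logistic in signed relevant evidence (slope 2/unit) and
weakly in irrelevant evidence (slope 0.2), with adaptation and switch terms
subtracting evidence in the correct direction (each 0.3–0.4 log-odds),
lowering accuracy; log-RT is linear in the regressors (relevant adaptation
+0.05, switch +0.03) plus a coherence term and Gaussian noise (SD 0.25 around
log 600 ms). These defaults encode the qualitative behavioural signature —
slower, less accurate responses when the relevant input or response was
already processed; the irrelevant input inert — at effect sizes a cohort of 22
subjects with 1024 trials each detects reliably.

## The estimator

For one subject/session, on correct trials only:

1. **Window averaging.** Windows of 150 ms ([c − 75, c + 75), half-open at the
   sample level so each 300 Hz window holds exactly 45 samples) stepped by
   33.3 ms over [−500, 1350] ms.
2. **Subsampling and penalty tuning.** Per window, ten subsamples of 90% of
   trials (without replacement); per subsample, ridge regression with the
   penalty chosen from {10⁻⁵, 10⁻³, 10⁻¹, 10¹, 10³, 10⁵} by 3-fold
   cross-validated squared error (the tuning loss is not stated by the study;
   squared error assumed), then a refit on the whole subsample.
3. **Aggregation.** Coefficients averaged across subsamples, absolute value
   last.

The ridge objective is $(1/2n)\lVert y - \beta_0 - X\beta\rVert^2 +
(\lambda/2)\lVert\beta\rVert^2$ with an unpenalized intercept — the per-sample
loss scaling makes grid values independent of the trial count. Regressors are
used as coded (0/1 or ±1, ±2) without z-scoring, so coefficient magnitudes are
comparable across equally coded regressors. Ties in the penalty search go to
the smallest grid value; CV folds are seeded.

**Sign alignment.** Sessions are aligned within the stated pairs (1 & 2,
3 & 4) by the Pearson correlation of their average evoked responses over
[−200, 1500] ms; a negative correlation flips the second session.

**Permutation inference.** The null is built by shuffling the *order of whole
design rows* relative to trials and re-running the full estimator — rows stay
intact, so all design correlations are preserved in every shuffle. With
several subjects the group statistic is the across-subject mean of absolute
coefficients, with independent seeded shuffles per subject (the study
specifies within-subject shuffling; the group combination is the package's
choice). P-values use the add-one rule, `p = (1 + #{null ≥ obs})/(n_perm +
1)`, so `p = 0` cannot occur. Significance is assessed inside a statistical
window of [−133.3, 950] ms at p < 0.001; the Bonferroni per-test alpha for the
conventionally quoted 29 centres is 0.05/29 ≈ 0.0017. The centre count is
*derived* from the grid (33 centres at a 33.3 ms step), not forced to 29;
`stat_window_centers()` reports the discrepancy when asked for the quoted
count.

**Peak latencies.** Leave-one-subject-out: the group peak is the argmax of the
other subjects' mean series; the held-out subject's peak is their own argmax
within ±66.7 ms of it (a ±133.6 ms variant is available). Ties break to the
earliest time. This anchors single-subject peaks against noise excursions
while leaving the estimate out-of-sample.

**Effect sizes.** Hedges' g uses the exact small-sample correction `J = 1 −
3/(4·df − 1)`; its CI is a seeded bias-corrected percentile bootstrap (10⁴
resamples) — the study does not state its CI method, and the bootstrap makes
no normality assumption. Repeated-measures ANOVAs report uncorrected degrees
of freedom (no sphericity correction, matching how the study reports F
statistics) and partial eta squared from each effect's own error stratum. A
zero effect sum of squares is reported as F = 0, p = 1 regardless of the error
term. The peak-time density utility (`peak_density()`) is for visualisation
only and enters no statistics.

## Behavioural analyses

Per subject, log-RT is regressed on the six regressors by ordinary least
squares over correct trials with RT in [150, 2000] ms (the study does not
state a trimming rule; bounds and the correct-only restriction are exposed as
arguments), and accuracy by unpenalized maximum-likelihood logistic
regression over all responded trials. A logistic fit showing separation
(non-convergence or |coefficient| > 15) is flagged and excluded from that
measure's group test. Group inference is a one-sample t with Hedges' g per
regressor. Psychometric fits regress the probability of the positive-pole
choice on signed relevant and irrelevant evidence per context; perfect
separation is reported via a flag rather than an error.

## Decoding

For multi-parcel epochs, choice direction is regressed out of every parcel's
windowed signal (residuals exactly orthogonal to choice), then relevant and
irrelevant input strength are decoded per context by ridge with nested
cross-validation: a seeded 10-fold outer split for performance, 3-fold inner
tuning over the same penalty grid. Residualization is fitted once on all
correct trials before splitting, mirroring the sequential description of the
procedure; a leakage-free variant (fit within training folds) is available
behind `leakage_free = TRUE` and is what calibration tests exercise when the
distinction matters.

The study does not name its decoding performance measure. The package reports
the Pearson correlation between pooled held-out predictions and targets, with
both centred within outer folds, plus R² as a secondary measure. Fold-centring
matters: raw pooled correlations are biased negative under the null because
ridge predictions shrink towards each training fold's mean, which
anti-correlates with the held-out fold. A smaller negative offset (about −0.04
at 24 trials per parcel) remains under label permutation from the
finite-sample anti-dependence of permuted labels across complementary folds;
it shrinks as trials-per-parcel grows and should be kept in mind when reading
absolute chance-level scores.

One structural consequence of residualization deserves emphasis. On correct
trials the relevant strength and choice correlate at 0.95 by design, so
removing choice removes ~90% of the relevant target's linearly decodable
variance — only the within-choice magnitude variation (±1 vs ±2) remains. A
generator with a 2:1 relevant:irrelevant loading ratio therefore yields
*lower* residualized relevant scores than irrelevant ones, whatever the
estimator does; the relevant-vs-irrelevant ordering reflects loadings directly
only when residualization is off. The package's recovery tests assert the
loading-ratio ordering on the full signal and, separately, the residualization
ordering itself (the choice shortcut is inflated without it and removed with
it). In real recordings the observed relevant > irrelevant decoding implies
relevant input coding strong enough to survive this 90% haircut — the
attenuation of irrelevant inputs is the scientific finding, not a property the
generator assumes.

## Degenerate inputs and numerical choices

- Window selection is half-open [c − hw, c + hw); an empty window names its
  centre in the error.
- `fit_ridge` requires finite inputs; `tune_lambda_cv` rejects a zero-variance
  response and returns a one-value grid directly.
- Schedules reject trial counts not divisible by 64, naming the remainder.
- Constant design columns make correlations undefined and error.
- Residualization requires both choice classes; outer CV folds with zero
  target variance error.
- Epoch files must carry a strictly increasing, uniformly spaced time axis;
  values round-trip bit-identically (17 significant digits).
- Seeds: one master seed per run; per-subject/session streams derive from it
  by fixed offsets, all below 2³¹.

## Test problem sizes

The study's headline statistics (22 subjects, 4 MEG sessions of 1024 trials,
1000 permutations, 38 parcels) are not desk-scale, so the package's recovery
and calibration tests run scaled-down versions chosen to preserve the relevant
ratios: permutation calibration uses 50 null datasets × 200 permutations at 64
trials and 5 window centres; peak-latency recovery uses 20 cohorts of 6
subjects × 192 trials (the closest balanced size to 200) on a [250, 750] ms
grid; decoding uses 8 parcels at 192 trials — about 24 trials per parcel,
matching the study's pooled-run ratio — and behavioural recovery uses the full
22 subjects × 1024 trials since it is cheap. Behavioural and permutation
false-positive rates are assessed against the 95% binomial band around the
nominal alpha aggregated over all tested cells.

## Known limitations

- The generator's kernels are smooth and regressor-locked; real evoked
  responses are neither strictly additive nor stationary in noise.
- Parcel data are simulated with independent noise per parcel; real source
  leakage induces spatial correlation the decoder could exploit or suffer
  from.
- The permutation null re-runs the full estimator and is expensive; the
  pipeline exposes `n_perm` and callers should scale it to their budget
  (the analysis convention is 1000).
- Bayesian ANOVAs, cluster-based corrections, beamforming and all sensor-space
  preprocessing are out of scope; the package starts from trial-locked source
  epochs.
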