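---
title: "Simulating and validating an adaptive inhibitory-control assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and validating an adaptive inhibitory-control assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freezeframe)
```

## The task and its staircase

The assessment measures speeded inhibitory control with a reverse go/no-go
design: respondents respond as quickly as possible to every foil image and
withhold the response whenever the designated target appears. Because the
motor response is prepotent (most trials are foils), withholding on the rare
target is the controlled, effortful act being measured.

Difficulty is controlled by the target frequency. The ladder holds seven
levels, `r paste0(100 * assessment_config()$level_ladder, "%", collapse = ", ")`,
ordered easiest to hardest: the rarer the target, the stronger the response
prepotency and the harder the withhold. A session plays five epochs of
thirty trials, starting at level 3 (30% targets). An epoch *passes* when the
proportion of targets correctly withheld **and** the proportion of foils
correctly responded to are both at least 0.80 — the comparison is inclusive,
so exactly 80% passes. A pass moves the next epoch one level harder, a fail
one level easier, clamped at both ends of the ladder. Two summary scores
come out of a session:

* the **raw threshold score**, an integer 1–7: we define it as the level the
  staircase would play next after the final epoch's adaptation (clamped).
  The alternative — the last level actually played — differs by at most one
  step; the post-adaptation definition is adopted because it makes the two
  boundary trajectories exact: a respondent who passes every epoch from the
  default start ends at 7, and one who fails every epoch ends at 1.
* the **session mean accuracy**, the percentage of correct trials over all
  150 trials. The deployed assessment converts thresholds to accuracy
  through a scoring table we do not have access to; the per-trial definition
  is our documented stand-in, and the raw threshold is always retained
  alongside it so nothing is lost.

### Trial scheduling

Within an epoch the number of targets is fixed at
`round-half-to-even(frequency × trials)` and positions are a uniform shuffle,
so the advertised frequency is realized exactly in every epoch rather than
only in expectation (with 30 trials: 12, 10, 9, 8, 6, 4, 3 targets across
the seven levels; the half-to-even rule decides the 10.5 and 7.5 cases).
There is no constraint against consecutive targets. Interstimulus intervals
are drawn from a *continuous* uniform distribution on [500, 1500] ms — the
unpredictability of onset timing is a design feature of the task, keeping
respondents in an alert state — and stimulus duration defaults to 500 ms
with the response window extending to the next onset. Session duration is an
emergent quantity: the sum of stimulus time, intervals, and response
latencies on responded trials. It is reported descriptively and no target
value is imposed on it.

### Reproducibility

All randomness in a session flows from the single `seed` in
`assessment_config()` through three named sub-streams (trial sequence,
intervals, respondent behaviour), derived by hashing the seed with the
stream label. Adding draws to one stream never perturbs another, and the
same configuration always reproduces the identical session, byte-for-byte
in its JSON log.

## Simulated respondents

Respondents convert a latent inhibition ability θ (unitless, higher =
better) into behaviour:

* **Targets**: withhold with probability `logistic(θ − d_l)`, where
  `d_l = δ (l − l₀)` is a linear per-level difficulty with slope δ = 0.9 per
  level, anchored at the default starting level l₀ = 3. The logistic link
  keeps probabilities in (0, 1) for finite ability and makes withholding
  strictly harder at lower target frequencies.
* **Foils**: respond with probability `1 − lapse`, default lapse 0.02 —
  a small attentional slip rate independent of level.
* **Latency**: log-normal with median ≈ 450 ms (sdlog 0.25), used only for
  the duration estimate.

The default ability, `qlogis(0.8) + δ ≈ 2.29`, places the 80% withhold point
exactly one level above the start, i.e. at mid-ladder — chosen so the
default staircase is informative (neither floor nor ceiling). These are
simulation choices, not estimates from human data: no sequential effects
(post-error slowing, vigilance decrement over the session) are modelled,
although time-on-task decline is a known feature of sustained-attention
tasks.

`deterministic_respondent()` is the fixture for exact staircase arithmetic:
in an epoch with *n* targets it withholds on exactly `ceiling(acc × n)` of
them (and analogously for foils). The ceiling guarantees the realized
proportion is at least the nominal one, so a respondent constructed *at* the
pass criterion passes under the inclusive rule — rounding to nearest would
realize 7/9 ≈ 0.78 at a nominal 0.80 on nine targets and spuriously fail.

## The synthetic cohort

`generate_cohort()` emulates a healthy older-adult baseline sample. Default
marginals: n = 92; age truncated-normal, mean 71.9, SD 4.86 years on
[65, 83]; 66% female; education truncated-normal, mean 16.45, SD 3.40 years
on [9, 27]; executive composite mean 0.43, SD 0.57 z-units; accuracy mean
92.01%, SD 4.70%. Truncation bounds are the observed ranges; truncated draws
are standardized against their analytic truncated-normal moments.

A single latent ability factor mediates every association — the simplest
structure consistent with pairwise correlation targets:

```
ability   = a·z_age + g·(female − p) + e·noise,   Var(ability) = 1
composite = r·ability + √(1 − r²)·noise₂          (rescaled to mean/SD)
accuracy  = clamp(μ_acc + σ_acc · ability, 0, 100)
```

with `g` the standardized female−male difference (default 0.35 — the
direction, women better, follows the validation evidence; the magnitude is a
simulation default because only direction and significance are reported),
`r` the Pearson target (0.26), and `a = 2 sin(π ρ_age / 6)` so the
*population Spearman* correlation of accuracy with age equals the configured
`ρ_age` (−0.22) — `ρ_age` is documented as a rank-correlation target, and
under a Gaussian copula the Pearson loading that produces a given Spearman ρ
is `2 sin(πρ/6)`. Education is generated independent of ability: its
association with accuracy was reported as null without a discussed sign, so
the generator does not impose one. Infeasible combinations (loadings
implying negative residual variance) raise a configuration error.

The clamp at 100 can place a small fraction of analytic accuracies exactly
at the ceiling (≈4% under the defaults); this mildly attenuates the Pearson
target and is visible in the report's ceiling proportion. We accept it
rather than re-shaping the accuracy distribution, since the score scale is
genuinely bounded.

**Missingness** is applied separately (`apply_missingness()`): each accuracy
is removed independently with probability 0.13, completely at random —
missing scores in the emulated study arose from administrative errors, and
no group differences were reported between participants with and without
scores, which is exactly the MCAR signature. Validation analyses use
complete cases only; nothing is imputed.

### Two accuracy routes

`generate_cohort()` fills accuracy *analytically* (affine in ability), which
gives exact control of the correlation structure and is the route used for
parameter-recovery checks. `simulate_cohort_sessions()` replaces it with
*engine-played* accuracy: latent ability maps affinely onto respondent
ability (`θ = 1.72 + 1.60 × ability`) and one full session is played per
participant. The offset and scale were calibrated once by a Monte-Carlo grid
against the configured accuracy mean and SD and then frozen; at cohort sizes
in the thousands the engine route's mean accuracy sits within about a
percentage point of the analytic target, while its SD runs slightly below
the configured 4.70 because per-session binomial trial noise (~2 points at
150 trials) is irreducible and the staircase compresses between-subject
spread near the ladder ends. The engine route is the one to use when the
question is about the *task* (trajectories, duration, threshold
distributions); the analytic route when it is about the *analysis pipeline*.

## The validation pipeline

`build_report()` reproduces a standard assessment-validation analysis on the
complete-case subset:

* descriptives of accuracy — mean, SD (n−1), range, adjusted Fisher–Pearson
  skewness G1 and sample excess kurtosis G2. The adjusted ("type 2")
  estimators are the common statistical-software default; the choice matters
  when comparing skew/kurtosis values across software.
* floor/ceiling: proportions exactly at the lowest and highest *possible*
  scores (0 and 100), plus counts at the *observed* extremes.
* Spearman ρ (midranks; two-sided p via the t approximation on n−2 df) for
  age and education; Wilcoxon rank-sum for gender; Pearson r (t on n−2 df)
  for the executive composite; and a simple regression of the composite on
  accuracy reporting R², `F = (n−2)R²/(1−R²)` on (1, n−2) df, and its
  p-value. All tests are two-sided at α = 0.05 with no multiplicity
  adjustment, matching how such validation results are conventionally
  reported.

The rank-sum test is exact — full enumeration of rank assignments — when
both groups have at most 10 observations and there are no ties (the
threshold is the `exact_max` argument); otherwise it uses the normal
approximation with tie-corrected variance and a continuity correction.
Degenerate inputs are handled explicitly: identical values across both
groups give p = 1 with a warning; zero-variance inputs to the correlations
and regression are errors; a gender group smaller than two drops the gender
comparison with a warning rather than failing the report.

These statistics are implemented directly (their exact p-value constructions
are part of the package's contract) and are verified in the test suite
against independent references: `cor.test`, `wilcox.test`, `lm`, `e1071`'s
moment estimators, brute-force enumeration, and closed-form covariance
formulas, plus a 10,000-replicate null calibration at n = 80 confirming
type-I error within [0.04, 0.06] for every test.

## What the simulations do and do not show

Problem sizes used in the test suite were chosen to bound Monte-Carlo error,
not to emulate any particular compute budget: parameter recovery at
n = 5000 (sampling SE of a correlation ≈ 0.014, so the ±0.03 check is a
~2 SE band); engine calibration at n = 2000 sessions; staircase
monotonicity over a 5-point ability grid × 500 sessions; missingness
calibration over 2000 cohorts; null calibration over 10,000 replicates.

Passing these checks shows the pipeline computes what it claims on data
whose generating process is known. It does **not** show that real
respondents behave like the logistic-ability model (no perceptual
similarity between specific target/foil images, no fatigue, no strategy
shifts), nor that the single-factor cohort structure is the true dependence
structure of any human sample — it is the minimal structure consistent with
the pairwise targets. Headline estimates from any real cohort (its mean
accuracy, its age and validity correlations) are properties of those human
data and are used here only as calibration targets for the generator: the
package reproduces the *computation*, verified on synthetic data, not the
human estimates themselves.

Other known limitations: the threshold-to-accuracy conversion is a stand-in
(see above); duration is emergent and its dispersion is driven entirely by
the latency model; and race/ethnicity composition of the emulated sample is
not modelled because no analysis in scope uses it.
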