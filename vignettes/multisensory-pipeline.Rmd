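---
title: "Methods: race-model, psychometric and flash-illusion analysis of multisensory behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-model, psychometric and flash-illusion analysis of multisensory behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisense)
```

## Scope and shape

`multisense` implements the behavioural analysis pipeline used to study
multisensory temporal processing in two-group intervention cohorts of
older adults: a redundant-signals response-time (RT) task analysed with
the race-model inequality, simultaneity (SJ) and temporal-order (TOJ)
judgments fitted with psychometric functions, and the sound-induced
flash illusion (SIFI) scored as accuracy per condition. Because the
original behavioural records of such studies are rarely deposited, the
package pairs every analysis stage with a synthetic-data generator whose
ground truth is known exactly, so the whole pipeline can be validated
end to end: estimator recovery, test size and power are all measurable
properties rather than assumptions.

The repository is organised as an analysis workflow: numbered scripts
under `analysis/` narrate a complete run over a simulated cohort, while
every computation they perform lives in package functions that the test
suite and `scripts/acceptance.R` exercise directly.

## Task designs

Four builders return the exact trial schedules, as pure functions of a
seed:

* **RT** — 150 main trials (50 each auditory A, visual V, audiovisual
  AV) plus 6 practice; 156 in total.
* **SIFI** — 166 trials: a 100-trial audiovisual block of ten cells
  (one-flash/one-beep at SOA 0; two-flash/two-beep at 70/150/230 ms;
  illusory one-flash/two-beep at ±70/±150/±230 ms), two 30-trial
  unimodal blocks (two flashes or two beeps at 70/150/230 ms), and 6
  practice trials. The visual unimodal trials are interleaved with the
  audiovisual block; the auditory block runs separately.
* **SJ / TOJ** — 7 SOAs {0, ±70, ±150, ±230} ms × 10 trials plus 6
  practice; 76 each. The two designs are structurally identical, so the
  same seed yields the same SOA sequence.

Sign convention: positive SOA = vision leads. Inter-trial intervals are
drawn uniformly on integer milliseconds in [1000, 3000] — the design
documents only a 1–3 s range, and a uniform integer draw is the least
committal reading. Practice trials are flagged and excluded from all
scoring.

Two design points were genuinely open and were fixed once:

* The 100-trial audiovisual SIFI block is read as 10 cells × 10
  repetitions, with the illusory condition carrying *signed* SOAs
  (auditory-lead and vision-lead each at three asynchronies) and the
  two-flash/two-beep control carrying unsigned ones. This is the only
  cell partition consistent with both the printed total and the
  signed-SOA convention.
* Whether the 2f2b control trials also varied lead order is not
  documented; they are generated lead-neutral here. Scoring is
  unaffected since accuracy is keyed by condition and |SOA|.

## The synthetic cohort

`sim_config()` fixes the cohort at 13 intervention
(physical-activity) and 14 control (reading) participants. The repeated
tasks (RT, SIFI) run at 8 sessions — baseline, three acute pre/post
pairs, post-intervention — and the judgment tasks at baseline and
post-intervention only.

**Response times.** Unimodal RTs are ex-Gaussian,
Normal(μ, σ) + Exp(τ), the standard skewed RT model. Defaults
(A: μ = 375, σ = 50, τ = 90 ms; V: μ = 400, σ = 55, τ = 100 ms, giving
channel means near 465 and 500 ms) describe a plausible older-adult
simple-RT regime. Audiovisual trials take the minimum of a channel pair
and subtract a coactivation shift *c* (default 50 ms): `AV = min(A*, V*)
− c`. With c = 0 this is a legal race that can never violate the Miller
bound in expectation; c > 0 produces early-quantile violations whose
magnitude scales with c — the simplest generator with an exactly
controllable violation. Channel pairs are drawn independently by
default; the `neg_dependent` option uses antithetic sampling (one
uniform u mapped through the ex-Gaussian quantile function for A and
1 − u for V), which pushes the audiovisual distribution toward the
bound's equality case. Draws outside (100, 3000) ms are redrawn,
reproducing the acquisition rule that such trials were repeated.

**Judgments.** SJ responses are Bernoulli draws from the same Gaussian
the analysis fits, `a·exp(−0.5((x−x0)/b)²)` (defaults a = 0.9,
x0 = 25 ms, b = 120 ms); TOJ responses from the logistic
`1/(1+exp(−(x−x0)/b))` (defaults x0 = −15 ms, b = 90 ms). Simulating
from the fitted family is deliberate: it makes parameter recovery a
clean estimator property, uncontaminated by model misspecification.

**Flash illusion.** No generative response model is documented for the
SIFI beyond accuracy, so the package supplies its own, labelled
synthetic truth: on illusory 1-flash/2-beep trials the probability of
reporting two flashes is `lapse + (1−lapse)·g0·exp(−|SOA|/τ_d)`
(defaults g0 = 0.6, τ_d = 150 ms, lapse = 0.02), an exponential decay
capturing the illusion's narrow temporal window; reports of three or
more stimuli occur with probability `p_report3` relative to an illusory
report; control and unimodal trials are correct with probability
1 − ε (ε = 0.03). These defaults are a stand-in, not estimates of any
study's parameters.

**Heterogeneity and effects.** Participants receive random trait
offsets (RT mean ± 30 ms SD, PSS ± 10 ms, log-width ± 0.12, illusion
strength ± 0.3 on the logit scale) so group summaries have realistic
between-subject variance. `session_effects` injects known group × phase
shifts (RT additive, coactivation additive, PSS additive, width and
illusion multiplicative) for power studies; the default is no effect.

All randomness descends from one master seed through hashed
per-participant, per-session, per-task substreams
(`substream_seed()`), so any slice of the dataset is reproducible in
isolation and two runs of the pipeline are byte-identical.

What the generator does **not** emulate: RT autocorrelation and fatigue
drifts, response omissions and anticipations beyond the redraw rule,
learning across sessions unless injected, SOA-dependent lapses, and any
causal-inference structure in the illusion. Passing tests therefore
certify the *estimators and tests*, not the realism of any particular
behavioural claim.

## Race-model-inequality analysis

The race model holds that redundant-signal responses come from the
faster of two unisensory channels, which implies Miller's bound
`F_AV(t) ≤ F_A(t) + F_V(t)` at every latency t. The pipeline:

1. **Trimming.** RTs below 100 ms or above 1500 ms are set to `Inf`
   rather than excluded, with strict inequalities (100 and 1500 ms are
   retained). Infinite entries stay in every CDF denominator, so a
   trimmed trial deflates the observed CDF instead of silently
   shrinking n.
2. **Vincentization.** Each participant's AV distribution is reduced to
   21 quantiles at 0, 5, …, 100% by linear interpolation between order
   statistics (0th = min, 100th = max; identical to base R's type-7
   rule, verified against it). Infinite entries occupy the top ranks,
   so quantiles beyond the finite fraction are `Inf`.
3. **Difference wave.** The three CDFs are compared at the
   participant's AV quantile times t_p, where observed(p) = p by
   construction and predicted(p) = min(F_A(t_p) + F_V(t_p), 1). The
   evaluation grid is a genuinely open choice (per-condition quantiles
   or a pooled time grid are defensible alternatives); evaluating at AV
   quantiles keeps observed and predicted on one axis and matches the
   per-bin probability-difference-wave presentation. d(p) =
   observed − predicted; d > 0 flags violation.
4. **AUC.** Violation magnitude is the trapezoidal sum of d over the
   fastest quartile: adjacent values at p ∈ {0, .05, .10, .15, .20,
   .25} averaged pairwise and the five averages summed. Units are
   probability × bin; the statistic is linear in d.
5. **Permutation test.** At each quartile bin a one-sample t statistic
   is computed across participants; the test statistic is tmax, the
   maximum over the six bins. The null flips the sign of each
   participant's whole difference vector — exhaustively (2^N patterns)
   for N ≤ 14, which covers both study groups, otherwise by seeded
   Monte Carlo (default 10,000). tcrit is the 95th percentile of
   permuted maxima; p is the one-sided proportion of permuted maxima at
   or above the observed tmax, with a 1e-9 tolerance so the identity
   pattern always counts (exhaustive p-values are exact multiples of
   2^−N and never below 2^−N). A zero-variance bin contributes t = 0
   with a warning — the relevant degenerate case is an all-zero d(0)
   bin, which arises whenever every participant's fastest AV response
   beats all unisensory ones. The test is run per group × session, as
   the two groups' outcomes are reported separately.

The sign-flip operates at participant level on the difference vectors.
The original trial-level formulation of the permutation scheme is a
known alternative; the participant-level form matches reporting one
tmax/tcrit/p per group per session and is exact under the same symmetry
assumption.

Mean/median RT summaries use finite values only — central tendency over
an infinite sentinel is meaningless — while the CDFs keep the sentinel
in the denominator; the two conventions serve different estimands.

## Psychometric fitting

Per-SOA proportions (of "simultaneous" for SJ, "vision first" for TOJ)
are fitted by *unweighted* least squares — matching the conventional
curve-fitting-software workflow these tasks are analysed with — to:

* Gaussian (SJ): `y = a·exp(−0.5((x−x0)/b)²)`, three free parameters;
* Logistic (TOJ): `y = 1/(1+exp(−(x−x0)/b))`, amplitude fixed at 1.

x0 is the point of subjective simultaneity (PSS); b is the width,
used as a proxy for the temporal binding window to avoid the
literature's inconsistent absolute definitions. Fitting is
Levenberg–Marquardt with bounds a ∈ (0, 1.2], x0 ∈ [−500, 500] ms,
b ∈ (1, 1000] ms (the bounded solver prevents degenerate widths), from
start values a₀ = max proportion, x0₀ = SOA of the maximum (SJ) or the
SOA nearest 0.5 (TOJ), b₀ = half the SOA range. Because a near-linear
stretch of curve can make the Jacobian numerically singular at one
start, a short ladder of fallback starts is tried and the lowest-RSS
convergent fit kept; non-convergence from every start yields an
excluded fit with r² = −∞. Proportions supplied on a 0–100 scale are
detected and rescaled, leaving x0 and b unchanged and a rescaled, so
the percent-vs-proportion notational ambiguity in how such curves are
written has no numerical consequence. No lapse parameter is fitted —
the model families have none.

Goodness of fit is r² = 1 − SS_res/SS_tot over the per-SOA
proportions, with flat data (SS_tot = 0) assigned r² = 0. Fits with
r² < 0.2 (strict; 0.2 exactly is retained) are flagged `excluded` and
dropped from group statistics, with each exclusion logged in the
pipeline report.

A caution established while validating this stage: with only 7 SOAs, a
three-parameter curve "explains" chance trends in the data of a purely
random responder often enough that the r² rule excludes roughly half of
them at 10 trials per SOA (an exactly flat responder is always
excluded). The rule is a coarse filter for degenerate observers, not a
reliable classifier — which is consistent with it removing only a
handful of participants in practice. Relatedly, at 100 trials/SOA the
PSS of the b = 80 ms logistic has a Cramér–Rao lower bound of ≈ 8 ms
SD at these SOAs, so no estimator can place it within ±10 ms more than
about 80% of the time; the package's tests document the achieved rates
rather than overstating them.

## Flash-illusion scoring

A trial is correct when the reported count equals the presented flash
count (audiovisual and visual blocks) or beep count (auditory block);
on illusory trials the veridical answer is 1, and reports ≥ 3 are
always incorrect. "Overall" accuracy pools all 100 audiovisual trials —
the unimodal blocks are analysed separately — so it equals the
trial-count-weighted mean of the 1f1b, 2f2b and illusory accuracies.
Per-SOA breakdowns are keyed by |SOA| with lead retained in the trial
records. Trials with missing responses leave both numerator and
denominator and are counted in the score's `n_dropped`.

## Difference scores and rank statistics

Difference scores are later minus earlier throughout: chronic =
post-intervention − baseline; acute_k = post − pre within acute pair k
(k = 1..3, identified by session stem). A missing side yields no score.
The sign convention means negative RT differences are improvements.

The Friedman test — used for accuracy-type outcomes whenever variance
homogeneity fails — is implemented directly as the tie-adjusted rank
statistic: within-block average ranks, χ² =
12·Σ(R_j − n(k+1)/2)² / [n·k·(k+1) − Σ(t³−t)/(k−1)] on k − 1 degrees
of freedom, with a fully tied table defined as χ² = 0, p = 1. It is
verified against `stats::friedman.test` on randomized tables, which
serves as an independent cross-check only. Heavier inferential
machinery (mixed-design ANOVA, covariate adjustment, sphericity
corrections, post-hoc procedures) is deliberately *not* re-implemented:
those are routine statistics available in any standard package, and the
report layer only records their delegation.

## Numerical choices and degenerate inputs

* Quantile interpolation is type-7; the fencepost (21 bins at 5%
  spacing) is pinned by tests.
* `Inf`-aware interpolation: a quantile touching an infinite order
  statistic with positive weight is `Inf`; with zero weight the finite
  neighbour is returned.
* Empty RT vectors, all-infinite modalities, fewer than two finite
  values, fewer than four informative SOAs, and incomplete Friedman
  blocks are all hard errors — silent imputation is never performed.
* Exhaustive sign-flip enumeration is capped at N = 14 (16,384
  patterns); beyond that the Monte Carlo path requires an explicit
  seed.
* The ex-Gaussian CDF is evaluated on the log scale so small τ cannot
  overflow the exponential term; σ = 0 and τ = 0 degenerate to the
  remaining component.

## Problem sizes used in validation

The test suite validates the race-model stage on 200 simulated
single-group cohorts (13 participants × 50 trials/modality) each for
the legal-race and coactivation conditions; psychometric recovery on
200 replicates at 100 trials/SOA; oracle agreement on 100 randomized
instances per primitive; and end-to-end determinism on the full
27-participant, 8-session default cohort. These sizes give Monte Carlo
standard errors small enough for the properties asserted (e.g. ±1.5%
on a 5% rejection rate) while keeping a full run on one CPU in the
low minutes.

## Known limitations

* The generator's coactivation is a constant shift of the race
  minimum; real coactivation models (superposition, interactive race)
  produce latency-dependent violations.
* The SIFI response model is the package's own synthetic stand-in.
* The participant-level sign-flip test assumes symmetric difference
  vectors under the null; trial-level permutation is not implemented.
* Unweighted least squares on proportions is statistically inefficient
  relative to binomial likelihood; it is retained deliberately for
  fidelity to the conventional workflow.
* Accuracy measures are analysed without correction for the bounded
  scale.
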