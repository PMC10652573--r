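# multisense

Analysis pipeline for multisensory temporal processing in behavioural
intervention studies: race-model-inequality analysis of redundant-signals
response times, psychometric fitting of simultaneity and temporal-order
judgments, and sound-induced flash illusion scoring — together with a
trial-level synthetic-data generator with known ground truth, so every
estimator and test in the pipeline is validated end to end.

It is written for researchers analysing audiovisual integration in
two-group repeated-measures designs (e.g. exercise or training
interventions in older adults), where the standard battery is exactly
these three task families.

## What it computes

**Race-model inequality (RMI).** The race model says the redundant
(audiovisual) response is won by the faster unisensory channel, which
implies Miller's bound at every latency *t*:

    F_AV(t) ≤ F_A(t) + F_V(t)

Each participant's RTs (trials outside [100, 1500] ms set to infinity,
not excluded) are Vincentized into 21 percentile bins; at the AV
quantile times the difference wave

    d(p) = p − min[ F_A(t_p) + F_V(t_p), 1 ]

is positive wherever the bound is violated (evidence of coactivation,
i.e. true multisensory integration). Violation magnitude is the
trapezoidal AUC of d over the fastest quartile (p ≤ 0.25), and the
group-level test is a max-t sign-flip permutation test (exhaustive
2^N for N ≤ 14) reporting `tmax`, the permutation critical value
`tcrit`, and a one-sided p.

**Psychometric fits.** Per-SOA response proportions are fitted by
bounded least squares to a Gaussian (simultaneity judgment)
`y = a·exp(−0.5((x−x0)/b)²)` and a fixed-amplitude logistic
(temporal-order judgment) `y = 1/(1+exp(−(x−x0)/b))`. `x0` is the point
of subjective simultaneity (PSS), `b` a proxy for the temporal binding
window (TBW); fits with r² < 0.2 are excluded.

**SIFI scoring.** Accuracy per condition (overall, 1-flash/1-beep,
2-flash/2-beep, illusory 1-flash/2-beep, unimodal visual/auditory) and
per |SOA|; low illusory accuracy indexes susceptibility to the
illusion.

**Aggregation.** Chronic (post-intervention − baseline) and acute
(post − pre per session pair) difference scores, group mean ± SE
summaries, and a tie-adjusted Friedman rank test.

## Worked example

```r
library(multisense)

cfg    <- sim_config(seed = 101)          # 13 + 14 participants, known truth
trials <- simulate_rt_dataset(cfg)        # redundant-signals task, 8 sessions
rmi    <- rmi_analysis(trials, seed = 101)
rmi$tests$physical_activity$baseline
#> <rmi_test> tmax=20.701 tcrit=1.988 p=0.0001221 (exhaustive, 8192 permutations)
#> mean first-quartile AUC = 0.5058 over 13 participants
```

The generator's default 50 ms coactivation speed-up makes the
audiovisual CDF beat the Miller bound in the fastest quartile: the
observed `tmax` (20.7) far exceeds the permutation critical value
(1.99), the p-value is the exhaustive minimum 2^−13 ≈ 0.00012, and the
mean first-quartile AUC of 0.51 probability·bin quantifies the
violation. Setting `coactivation_shift_ms = 0` yields a legal race:
`d(p)` stays at or below zero on average and rejections fall to the
nominal 5% rate.

```r
sj <- fit_judgment_task(simulate_sj_dataset(cfg), "SJ")
sj[1, c("participant_id", "a", "pss", "b", "r2", "excluded")]
#>   participant_id     a   pss     b     r2 excluded
#> 1            P01 1.003 33.55 105.8 0.9302    FALSE
```

The Gaussian fit recovers this participant's simultaneity profile
(cohort truth: a = 0.9, PSS = 25 ms, b = 120 ms, plus per-participant
trait offsets); `b` is the TBW proxy carried into the group contrasts.

A complete narrated run — simulation, race-model tests per group ×
session, psychometric fits, SIFI scoring, difference scores and the
group report — is in the numbered scripts under `analysis/`
(`Rscript analysis/01_simulate.R`, then `02`–`05`; tables land in
`results/`).

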