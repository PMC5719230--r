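---
title: "Models and methods behind stopgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stopgame)
```

## The problem

Longitudinal web-based cognitive testing loses participants: each day of a
multi-session study, some fraction simply stops coming back. Gamified task
variants (points, themes) are a popular proposed remedy, but evaluating
them requires jointly analyzing attrition (a survival problem), subjective
engagement (questionnaires), objective engagement proxies (reaction-time
variability, loss-of-focus events) and the task's cognitive outcome — the
stop signal reaction time (SSRT) — while respecting the exclusion rules
that make SSRT estimates valid. `stopgame` implements that full pipeline,
together with a simulator that generates cohorts whose true parameters are
known, so every estimator in the pipeline can be validated by parameter
recovery rather than by eyeballing.

## The race model and SSRT

The Stop Signal Task presents a stream of choice ("go") trials; on 25% of
trials a stop signal appears after a stop signal delay (SSD) and the
participant must withhold the prepared response. The standard account is
an *independent horse race*: a go process with finishing time $T_{go}$
races a stop process that starts at the SSD and needs $T_{stop}$ ms. The
participant responds iff

$$T_{go} < \mathrm{SSD} + T_{stop},$$

so the probability of responding (the *inhibition function*) increases
monotonically in SSD, failed-stop responses are the fast tail of the go
distribution (hence faster than go responses on average), and the latent
stopping latency $E[T_{stop}]$ — the SSRT — can be recovered from
behaviour even though it is never directly observed.

`stopgame` estimates SSRT per session by the 50%-inhibition method:

1. drop anticipatory responses (RT < 150 ms, strict);
2. check the race model (below); exclude the session if it fails;
3. fit a logistic inhibition function $P(\mathrm{respond}\mid\mathrm{SSD})$
   by maximum likelihood over the session's stop trials and read off
   `ssd50`, the SSD at fitted probability one half;
4. `ssrt = median(go RT) − ssd50`.

The subtraction convention follows from the race: at the SSD where the
race is tied half the time, the go median equals `ssd50` plus the stopping
latency. Session SSRTs are averaged over the first four (compulsory)
sessions per participant; a participant whose four compulsory sessions all
fail the race checks is flagged and dropped from the SSRT analysis.

### Race-model checks

Three checks run in order; the first failure is recorded as the session's
exclusion reason:

* `race_rt_order` — median failed-stop RT must be strictly below the
  median go RT. The published exclusion sentence this rule derives from
  reads inverted relative to the race-model prediction; the package
  defaults to the standard direction and provides `verbatim_rt_rule =
  TRUE` to apply the sentence literally. The two readings are deliberately
  not reconciled — switching modes flips which sessions are excluded, and
  the choice is surfaced as configuration rather than hidden.
* `ssd_rt_corr` — Spearman correlation of per-SSD median failed-stop RT
  with SSD must be positive (sign only; no significance threshold).
* `ssd_acc_corr` — Spearman correlation of per-SSD inhibition rate with
  SSD must be negative.

Checks need at least 10 stop-trial responses and 3 distinct SSD values
(both configurable); anything less is `insufficient_data`. Responses that
land before the SSD (`stop_presignal`) count as stop-trial responses for
the inhibition function by default — the go process won the race — with a
switch to drop them.

### Known estimation bias

The true inhibition function is the CDF of $T_{go} - T_{stop}$, which is
skewed because $T_{go}$ is ex-Gaussian; the symmetric logistic link
therefore misplaces the 50% point slightly. In recovery experiments (50
simulated participants, true stopping latencies uniform on 200–320 ms,
four 240-trial sessions each) the estimator shows a mean absolute error of
about 14 ms, a recovery slope near 0.98, and a small negative bias of
roughly −12 ms. This is the accuracy regime users should expect from
240-trial sessions with staircased SSDs.

## The task engine

* **Schedule**: five blocks of 48 trials; exactly
  `round(0.25 × 48) = 12` stop trials per block, positions shuffled
  uniformly within block. Counts are exact rather than Bernoulli because
  the design fixes the stop fraction. Identical seeds give identical
  schedules.
* **Staircases**: the SSD is tracked by four independent 1-up/1-down
  staircases started at 50/150/250/350 ms (step 50 ms, clipped to
  [0, 800] ms) and assigned to stop trials round-robin. This is the
  simplest scheme that samples the inhibition-probability-by-SSD space on
  both sides of the participant's 50% point: each staircase equilibrates
  where its own response probability is one half, and the spread of
  starting points covers the curve early in the session. The original
  task's exact staircase parameters were not recoverable, so these values
  are the package's own defaults, exposed in `task_config()`.
* **Scoring** (points variant): a successful go response earns
  `0.2 × bonus × (800 − RT)` points (zero beyond 800 ms); the bonus rises
  by 1 after every 3 scored responses, falls by 3 on a failed stop trial,
  is unchanged on a successful inhibition, and never drops below 1.
  Two ambiguities had to be resolved: which trials advance the "every 3
  trials" counter (here: scored go-type responses only — errors, omissions
  and stop trials neither advance nor reset it), and whether a response
  made before the stop signal appeared earns points (here: yes — to the
  participant the trial is indistinguishable from a go trial, and the
  bonus is explicitly not lost). The bonus starts at 1 each session;
  scores reset per session while the high score persists. The trial log
  stores points at full precision; `round_half_up()` exists only for
  display.

## The cohort simulator

`generate_cohort()` draws per-participant profiles and simulates every
trial of every session, producing three tables: a trial log, a session log
(calendar day, questionnaire, loss-of-focus count) and a *truth table*
holding each participant's generating parameters. Defaults, and why:

| Parameter | Default | Rationale |
|---|---|---|
| go RT | ex-Gaussian μ = 380, σ = 50, τ = 120 ms | the standard RT model; mean 500 ms sits in the plausible range for a speeded two-choice task |
| stopping latency | normal, mean 270 ms (SD 20 trial-to-trial, 40 between participants) | centre of the 250–290 ms range typical of adult SSRTs |
| lapse / wrong-key rates | 0.02 / 0.02 | rare but non-zero, so omissions and errors occur |
| dropout hazard per optional day | 0.160 / 0.152 / 0.115 (nongame / points / theme) | chosen so the expected mean sessions completed are 7.4 / 7.5 / 8.0 across the three variants — realistic levels for a paid daily study; configurable per-day vectors are supported |
| questionnaire | session-1 means 56/58/53, session-4 means 50/52/51 (0–100), item SD 20 | enjoyment ratings in the mid-50s that decline over the compulsory block, with the points variant rated highest |
| loss of focus | Poisson, 0.95/session | less than one event per session, matching how rare tab-switching is in practice |

Attrition is memoryless given the hazard: the four compulsory sessions
always run, then each optional day is attempted with probability
`1 − hazard` given the previous one was. Under a constant hazard $h$ the
expected number of sessions is $4 + \sum_{k=1}^{6}(1-h)^k$ — the closed
form the tests check against. Optional non-conformance injection
(`p_noncompliance`) inserts 1–2 day calendar gaps into the compulsory
block to exercise the conforming / loosely-conforming / non-conforming
classification.

All randomness flows from one root seed through named substreams
(`schedule`, `responses`, `questionnaire`, `focus`, `attrition`,
`calendar`; see `substream_seed()`), so reruns are byte-identical and each
component is independently reproducible.

**What the simulator does not emulate** — and hence what passing recovery
tests do *not* establish about real data: RT autocorrelation, practice and
fatigue within or across sessions, strategic slowing in anticipation of
stop signals (which violates race independence), context-dependent
dropout (e.g. quitting after a bad session), device/browser timing noise,
and item-level questionnaire structure. Sessions are generated complete;
started-but-unfinished sessions can be represented in the session log
(`completed = FALSE`) and are excluded before estimation, but the
simulator does not produce them by default.

## The inferential layer

* **Survival**: `km_estimate()` and `logrank_test()` wrap the standard
  product-limit and log-rank machinery from the `survival` package (the
  test suite checks them against a hand-rolled product-limit oracle).
  Survival time is the number of completed sessions; participants reaching
  the 10-session design maximum are right-censored by default, since the
  study ending is not a dropout event — `censor_at = NULL` treats every
  time as an event for sensitivity analysis.
* **ANOVAs**: one-way ANOVA reports partial
  $\eta^2 = SS_b/(SS_b+SS_w)$. The mixed design (2 within-levels ×
  variant) is computed by its exact decomposition — subject means carry
  the between effect, difference scores carry the time effect and
  interaction — with the time effect tested against the unweighted grand
  mean of group differences (the Type III convention, which matters only
  under unbalance). With two within-levels sphericity holds automatically,
  so no correction is needed or applied.
* **Post hoc t tests**: Student's pooled-variance t (df = n₁+n₂−2, the
  convention matching this literature's reported dfs), Cohen's d from the
  pooled SD, no multiplicity correction (mirroring the reporting style the
  pipeline reproduces); a Welch switch is provided.
* **JZS Bayes factor**: the default two-sample Bayes factor with a Cauchy
  prior (scale r = 0.707, "medium-large effects expected") on the
  standardized effect, computed as a one-dimensional integral over
  Zellner's g with the inverse-gamma(1/2, r²/2) mixing density, by
  adaptive quadrature at tolerance 1e−8 (a fixed-grid fallback on
  u = g/(1+g) engages, with a warning, if adaptive quadrature fails).
  BF10 in [1/3, 3] supports neither hypothesis; [0.1, 1/3) or (3, 10]
  is "Positive", [0.01, 0.1) or (10, 100] "Strong", beyond that
  "Decisive". The implementation is cross-checked against an independent
  quadrature of the noncentral-t likelihood against the Cauchy prior.
* **Power**: `chisq_power_n()` finds the smallest n whose noncentral
  chi-square (λ = nφ²) exceeds the target power at the central critical
  value, by doubling plus bisection (power is monotone in n); `groups = 3`
  rounds up for equal group sizes.

## Numerical choices and degenerate inputs

* Inhibition-function separation (every response SSD above every
  inhibition SSD) is detected before fitting; the fit is flagged
  unconverged and `ssd50` falls back to the midpoint between the highest
  all-inhibit and lowest all-respond SSD.
* A non-positive fitted slope marks the fit unconverged (the session is
  then `insufficient_data`); the monotone direction is not forced.
* Spearman checks are sign tests only — a zero or undefined correlation
  (e.g. constant inhibition rate) fails the corresponding check.
* Outlier screening removes participants more than 4 IQRs from the sample
  median on mean RT or accuracy; a degenerate IQR of 0 keeps exact-median
  values only and warns.
* Logistic-regression separation is flagged via the fitted-probability
  warning and an effect-size sanity bound rather than silently reported.
* Truncated draws (RTs in (0, 900], stopping latencies > 0) use
  resampling, preserving the distribution's shape within the window.

## Problem sizes used in validation

The shipped test suite validates at desk scale: SSRT recovery uses 50
participants × 4 sessions × 240 trials; type-I error uses 1,000 null
cohorts of 291 participants (attrition draws only); Bayes-factor
agreement uses a 15-point (t, n₁, n₂) grid at 1% tolerance; Kaplan–Meier
agreement uses 100 random datasets of up to 25 participants. These sizes
make the full suite run in well under a minute of simulation time while
keeping Monte-Carlo error far below the asserted tolerances.

## Limitations

* SSRT estimates carry the small negative bias described above; analyses
  of *differences* between variants are unaffected, absolute levels
  slightly so.
* The constant-hazard attrition model cannot produce the hump-shaped or
  stabilizing dropout patterns real cohorts sometimes show; day-varying
  hazard vectors are accepted but the defaults are flat.
* The mixed ANOVA handles exactly two within-subject levels (which is all
  the session-1/session-4 design needs); more levels would require
  sphericity handling the package does not implement.
* Integration-method SSRT estimators and hierarchical Bayesian SSRT models
  are out of scope.
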