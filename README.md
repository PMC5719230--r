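# stopgame

Simulation and analysis of longitudinal, web-based **Stop Signal Task
(SST)** studies that compare gamified task variants (a plain control, a
points-scored variant, a graphically themed variant). The package is aimed
at researchers who run remote cognitive testing over repeated daily
sessions and need to study **participant attrition**, **engagement** and
**response inhibition** together — including at the design stage, before
any human data exist.

## What it does

Real multi-day cohorts are expensive and their raw data are often access
restricted, so every stage of the pipeline here runs against a synthetic
cohort with known ground truth:

* **Task engine** — deterministic trial scheduling (five blocks of 48
  trials, 25% stop trials), four 1-up/1-down staircases tracking the stop
  signal delay (SSD), and the points-variant scoring state machine
  (`points = 0.2 × bonus × (800 − RT)`; bonus +1 every 3 scored responses,
  −3 on a failed stop, floor 1).
* **Cohort simulator** — independent-race trial behaviour (ex-Gaussian go
  process racing a stopping process), per-variant daily dropout hazards
  over a 4-compulsory + 6-optional session design, visual-analog
  questionnaires on a 0–100 scale, and Poisson loss-of-focus counts. Every
  generated quantity the analysis later estimates is written to a truth
  table.
* **SSRT estimation** — per-session stop signal reaction time via an
  inhibition function: a logistic fit of P(respond) against SSD gives the
  SSD at 50% inhibition (SSD50), and

  ```
  SSRT = median go RT − SSD50
  ```

  with anticipatory responses (< 150 ms) filtered and sessions violating
  the race model excluded (failed-stop RTs must be faster than go RTs,
  failed-stop RTs must rise with SSD, inhibition rate must fall with SSD).
* **Engagement & attrition** — questionnaire scoring with reverse-scored
  items, conformance classification (4 sessions in 4 consecutive days;
  loosely conforming within 5 days), per-variant survival percentages.
* **Inference** — Kaplan–Meier estimates and log-rank tests, one-way and
  mixed (2 × variant) ANOVAs with partial η², pooled-variance post hoc
  *t* tests with Cohen's *d*, JZS Bayes-factor *t* tests (Cauchy prior,
  r = 0.707), logistic regression of next-day return, and noncentral
  chi-square power / sample-size calculation.

## Worked example

```r
library(stopgame)

cfg <- run_config(seed = 42, cohort = list(n_per_variant = 30))
dir <- file.path(tempdir(), "demo_study")
simulate_study(cfg, dir)      # writes trials.csv, sessions.csv, truth.csv
an <- analyze_study(dir, cfg)

an$tests$logrank
#> log-rank: statistic=8.367, df=2, p=0.01524
an$tests$anova_sessions
#> one-way ANOVA: statistic=5.39, df=2,87, p=0.006214, partial_eta_sq=0.1102
an$tests$bayes_sessions$nongame_vs_points
#> JZS Bayes factor: BF10=21.85 (r=0.707, t=-3.330, df=58)
#>   evidence: Strong (favors H1)
an$attrition$means
#>   variant  n mean_sessions    ci_lo    ci_hi
#> 1 nongame 30      6.933333 5.982931 7.883735
#> 2  points 30      8.866667 8.154568 9.578765
#> 3   theme 30      7.800000 6.920723 8.679277
```

The default simulator gives the three variants *different* dropout hazards
(0.160 / 0.152 / 0.115 per optional day), so at this seed the log-rank
genuinely detects the difference: variants differ in mean sessions
completed, and the Bayes factor reports strong evidence that nongame and
points differ. Per-session estimates sit beside the tests:

```r
head(an$summaries[, c("participant_id", "session_number", "valid",
                      "exclusion_reason", "ssrt_ms", "cv_percent")])
#>   participant_id session_number valid exclusion_reason  ssrt_ms cv_percent
#> 1           P001              1  TRUE             none 326.0286   22.97074
#> 2           P001              2  TRUE             none 366.0318   22.85687
#> ...
```

Here 51 of 708 sessions (~7%) fail a race-model check and carry an
`exclusion_reason` instead of an SSRT. Sample-size planning is one call:

```r
chisq_power_n(phi = 0.231, df = 2, alpha = 0.05, power = 0.95)
#> [1] 290
chisq_power_n(0.231, 2, groups = 3)   # next multiple of 3 for equal groups
#> [1] 291
```

A thin command-line front end is installed at `inst/cli/stopgame`
(`simulate`, `analyze`, `power`, `report` subcommands).

## Documentation

The methods vignette (`vignettes/stopgame-methods.Rmd`) describes the race
model, the staircase and scoring rules, what the simulator does and does
not emulate, the estimation conventions and their known biases, and the
numerical choices behind the inferential layer.
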