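# ehengage

Engagement, nonuse attrition and dose-response analysis for eHealth
intervention trials.

Long-running web-based lifestyle interventions generate raw usage logs —
logins, goals set, messages to a coach, self-monitoring entries, education
pages read — and the central analytical questions are always the same: *how
engaged was each participant, who disengaged and when, which baseline
characteristics predict engagement, and did engagement translate into better
outcomes?* `ehengage` packages that entire analysis chain for
biostatisticians and trial analysts, together with a synthetic trial
generator with planted effects so every estimator can be validated without
access to individual-level trial data.

## What it computes

**Composite engagement score (0–7).** Login tertile points (0/1/2,
nearest-rank tertiles of total logins), goal points (0 / 1 / ≥2 → 0/1/2),
and one point each for any coach message, any monitoring measurement, and
any education material read. Scores are categorised as low (0–2), moderate
(3–5) or high (6–7), with an equal-frequency tertile categorisation as a
sensitivity variant.

**Nonuse attrition.** The event time is the first 30-day window of
follow-up with no qualifying platform login (logins made only for scheduled
questionnaires do not qualify); events in months 1–2 are *early* attrition,
later events *late*, and event-free participants are *highly consistent
users*. A 6-week window and a sliding-gap rule are available as sensitivity
definitions.

**Predictors of engagement.** A from-scratch generalized ordered logit
(partial proportional odds) model

  P(Y > j | x) = logit⁻¹(αⱼ + x′βⱼ),  j = 1, 2

with per-term Wald tests of the parallel-lines assumption (terms passing
share one coefficient; violating terms get split-specific ones), bivariate
screening at p < .2 and manual backward elimination at p > .05.

**Predictors of attrition.** Cox proportional-hazards models (own
partial-likelihood fitter, Efron or Breslow ties, delayed entry), a
Grambsch–Therneau Schoenfeld-residual diagnostic, and the early/late
follow-up split at month 2 used when proportional hazards fails over the
full period.

**Dose-response outcome contrasts.** Adjusted mean differences in 18-month
change versus the control arm for low/moderate/high engagement, per outcome
(composite cardiovascular z-score from SBP, LDL and BMI changes, plus each
component, physical activity, diet adherence, and dementia/CVD risk
scores), with a joint F-test across the three category terms.

## Worked example

```r
library(ehengage)
library(dplyr)

cfg   <- sim_config(seed = 2025, n_intervention = 600, n_control = 500)
trial <- simulate_trial(cfg)

count(trial$engagement, category)
#>   category     n
#> 1 low         63
#> 2 moderate   317
#> 3 high       220

rec <- attrition_records(trial$usage$logins,
                         filter(trial$participants, arm == "intervention"))
classify_consistency(rec)
#>   group                  n  share
#> 1 early                184 0.307
#> 2 late                 325 0.542
#> 3 consistent            91 0.152
#> 4 consistent_dropped    20 0.0333
```

About 31% of intervention participants stop using the platform within two
months and 54% later on, while 15% log in every month they are enrolled —
the characteristic reverse-sigmoidal attrition pattern of digital
interventions (`plot_attrition_curve(rec)` draws it).

```r
d <- trial$participants %>%
  filter(arm == "intervention") %>%
  left_join(select(trial$engagement, participant_id, category),
            by = "participant_id")
fit <- gologit(category ~ computer_use + cognition_z, d)
tidy(fit, exponentiate = TRUE)
#>   term                  equation estimate conf.low conf.high
#> 1 alpha_1               eq1          1.00   0.0656      1.94
#> 2 alpha_2               eq2         -1.79  -2.74       -0.845
#> 3 computer_uselt7h_week all          3.34   1.28        8.73
#> 4 computer_usege7h_week all          3.76   1.42        9.99
#> 5 cognition_z           all          1.82   1.39        2.39
```

Both computer-use terms satisfy the parallel-lines assumption here
(`wald_parallel_lines(fit, "computer_use")$p.value` ≈ 0.98), so each gets a
single odds ratio: participants using a computer < 7 h/week before baseline
have 3.3 times the odds of higher engagement than non-users in this
simulated cohort (the generator plants OR 5.39 on the latent propensity;
the induced ordinal OR on a 600-person cohort is estimated with wide
uncertainty).

```r
adata <- trial$participants %>%
  left_join(select(trial$engagement, participant_id, category),
            by = "participant_id") %>%
  mutate(engagement_group = ifelse(arm == "control", "control",
                                   as.character(category))) %>%
  left_join(composite_z_change(outcomes_wide(trial$outcomes)),
            by = "participant_id")
fit_change_model(adata, "composite_z_change")
#> 18-month change model for `composite_z_change` (n=1100, overall p=0.001621)
#>   group    estimate conf.low conf.high p.value
#> 1 low        0.0161  -0.0860    0.118  0.758
#> 2 moderate  -0.0776  -0.132    -0.0228 0.00558
#> 3 high      -0.104   -0.166    -0.0414 0.00112
```

Negative differences mean greater improvement than control: the composite
cardiovascular z-score improves by 0.10 SD-units more in high engagers than
controls (planted truth −0.08), with a clear dose-response gradient
(overall p = 0.0016) and no benefit in low engagers — the pattern the
analysis chain is designed to detect.

`run_pipeline(config = cfg, out_dir = "out")` runs every stage in sequence
and writes `engagement.csv`, `attrition.csv`, `predictors_model.json`,
`survival_models.json`, `outcome_models.csv`, a text summary and a seed- and
hash-stamped manifest; `run_pipeline(input_dir = ...)` does the same from
prepared CSVs in the canonical schema (see `?read_usage_dir`). A thin
command-line wrapper lives at `inst/scripts/engage.R`.

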