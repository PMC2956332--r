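# lipidtrial

Many adults who would benefit from cholesterol-lowering treatment are
untreated, or treated but not reaching guideline lipid targets. One proposed
remedy is a consumer-facing website that turns a short questionnaire into
immediate, individually tailored advice — *you appear to qualify for statin
therapy; your level is above target; lose weight, exercise, switch
margarine* — which the person can take to their doctor. Whether such advice
actually changes treatment is a question for a randomized controlled trial.

`lipidtrial` is an R package for designing, simulating and analysing exactly
that kind of trial. It provides, as composable tidyverse-style functions:

* **A deterministic tailored-advice engine.** Questionnaire records (with
  explicit yes/no/unanswered tri-states) are imputed by the
  "blank-means-no, except lipids" rule, screened for statin eligibility and
  lipid-target attainment against a *configurable* guideline rule set
  (first-matching-rule semantics, total-cholesterol/LDL thresholds in
  mmol/L), flagged for familial hypercholesterolemia risk, given lifestyle
  recommendations (weight loss if BMI > 24 and not already trying,
  exercise, diet, cholesterol-lowering margarine), and rendered as
  plain-text letters. The shipped rule set is a clearly labelled synthetic
  reconstruction of the mid-2000s Australian guidelines; swap in your own
  as JSON.
* **A synthetic cohort generator** calibrated to the published trial's
  marginal structure: baseline prevalences and means/SDs, heavy lipid
  under-reporting (~57% report a recent total cholesterol), 93% follow-up
  completeness, response latency with median 10 weeks and floor 7, and
  arm-specific outcome probabilities on the intention-to-treat scale.
* **The trial statistics.** Differences in proportions with unpooled Wald
  confidence intervals
  (`diff ± z·√(p̂₁(1−p̂₁)/n₁ + p̂₂(1−p̂₂)/n₂)`), the 2×2 Pearson chi-square
  without continuity correction (`χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`),
  Welch *t* contrasts for continuous outcomes, and two-proportion z-test
  power and sample size. Results come back as broom-style objects with
  `tidy()`/`glance()` methods.
* **Pipeline orchestration**: simple 1:1 randomization, arm-dependent
  advice delivery, intention-to-treat outcome tables with full randomized
  denominators, baseline characteristic tables with guideline-derived rows,
  forest plots, and a reproducible end-to-end `run_pipeline()`.

## Worked example

The published primary outcome — 64 of 1062 intervention participants versus
79 of 1037 controls commencing or increasing lipid-lowering treatment:

```r
library(lipidtrial)
proportion_difference(64, 1062, 79, 1037)
#> Difference in proportions: 64/1062 (6.0%) vs 79/1037 (7.6%)
#>   diff -1.59 pct points, 95% CI (-3.75, 0.57)
#>   Pearson chi-square 2.094, p = 0.1479
```

The intervention arm had 1.6 percentage points *fewer* treatment changes;
the interval spans zero and the chi-square p rounds to .15, so no effect is
detectable. The design calculation that sized such a trial:

```r
required_n_per_group(p_control = 0.05, delta = 0.025, alpha = 0.05, power = 0.90)
#> [1] 1969    # 3938 participants in total
```

A full synthetic trial, end to end:

```r
baseline <- generate_baseline(cohort_spec(2099), seed = 11)
trial    <- randomize_arms(baseline, seed = 12) |>
            generate_followup(outcome_spec(), seed = 13)
itt_outcome_table(trial)
#> # A tibble: 12 × 14
#>    outcome        x1    n1    x2    n2 diff_pct ci_low_pct ci_high_pct  p_value
#>  1 primary        62  1056    77  1043  -1.51       -3.64        0.617 1.64e- 1
#>  2 commenced_t…   31  1056    38  1043  -0.708      -2.23        0.819 3.63e- 1
#>  ...
#> 12 referred_fr…  198  1056    84  1043  10.7         7.82       13.6   6.73e-13
```

(the simulated trial reproduces the structure of the published one: a null
primary outcome, and a strongly positive friend/relative referral outcome).
`autoplot()` on that table draws the forest plot. Tailored advice for one
participant:

```r
cat(render_letters(generate_advice(baseline[3, ]))$letter)
#> Dear participant P000003,
#> ...
#> Recommendations:
#>   * Weight loss
#>   * Healthy diet
#> Why:
#>   - Your body mass index is above 24 and you are not currently trying to lose weight.
#> ...
#> Please note: this advice may not take into account your full medical history.
```

A thin command-line wrapper with `simulate`, `advise`, `analyze`, `power`
and `run` subcommands ships in `inst/exec/lipidtrial`.

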