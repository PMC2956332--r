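---
title: "Simulating and analysing a tailored cholesterol-advice trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a tailored cholesterol-advice trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtrial)
library(dplyr)
```

This vignette is the package's own account of its methods: the advice
algorithm and its rule semantics, the statistical model of the two-arm
trial, the synthetic-data generator and what it does and does not emulate,
and the numerical and design choices that were genuinely open.

## The advice algorithm

The engine is a deterministic rule cascade over a participant's
questionnaire record. Its stages, each a pure function:

1. **Imputation.** Every unanswered yes/no question is assumed to be "no".
   Lipid values are the exception: an absent cholesterol level is never
   guessed, because the correct response to a missing lipid is qualified
   advice plus a recommendation to get measured, not a fabricated value.
   Keeping raw records tri-state (`TRUE`/`FALSE`/`NA`) and imputation as a
   separate, observable step (`impute_missing()`) makes this policy
   testable: the suite verifies that answering "no" explicitly and leaving
   a question blank produce identical advice for every non-lipid field.

2. **Statin eligibility** (untreated participants). The record is matched
   against an ordered list of eligibility rules; the *first* rule whose
   predicate holds (any of its history/demographic flags true; an empty
   predicate matches everyone) governs, and the record qualifies if total
   cholesterol or LDL reaches that rule's threshold. Screening uses the
   larger of highest-ever and recent total cholesterol — eligibility is
   about levels that ever qualified a person — while target attainment
   (below) uses recent values only, because targets concern current
   control. If the governing rule needs a lipid value that is missing, the
   classification is *indeterminate* rather than a guess.

3. **Target attainment** (treated participants). Same first-match
   semantics against ceiling rules. A value exactly at the target counts
   as *at* target: recommending a treatment increase requires being
   strictly above. All printed thresholds in the lifestyle and familial
   rules are likewise strict (`BMI > 24`, `TC > 9`), read literally and
   boundary-tested.

4. **Lifestyle rules.** Weight loss if BMI (always derived from weight and
   height, never stored) exceeds 24 and the person is not already trying;
   exercise and diet whenever not already reported; margarine for
   non-users with a high-cholesterol diagnosis or a positive eligibility
   finding. An unknown BMI triggers nothing.

5. **Familial-risk flag.** Total cholesterol above 9 mmol/L, aboriginal
   heritage, a reported genetic hypercholesterolemia, a diagnosed familial
   hypercholesterolemia, or a family history of premature coronary disease
   *combined with* a personal high-cholesterol diagnosis. The personal FH
   diagnosis is included as a trigger in its own right: a diagnosed
   heritable condition trivially implies a familial tendency.

The drug recommendation is then `start_statin` (untreated, eligible),
`increase_statin` (treated, above target), `indeterminate_lipids` (the
governing classification needed a missing lipid; the plan sets
`measure_lipids`), or `no_change`. Indeterminacy is reported *only* when
the decision was actually blocked: if a non-lipid pathway resolves the
decision, the plan resolves.

### The guideline rule set is configuration, not fact

The original advice service classified against the February 2004
Pharmaceutical Benefits Scheme eligibility criteria and the 2001 CSANZ
lipid targets. The contents of those documents are not reproduced here;
encoding them as package constants would present a reconstruction as
authority. Instead the thresholds live entirely in a `guideline_rules`
object (JSON on disk, schema documented in `?read_guidelines`), and the
package ships one default, labelled a synthetic reconstruction in both its
`version_label` and its filename
(`inst/extdata/guidelines-default-synthetic.json`). All tests run against
that default; any other vintage can be swapped in without touching code.

### Scenario testing

The engine is verified over an exhaustive cross-product grid of the seven
decision-driving flags (treatment status, the four secondary-prevention
conditions collapsed to their representatives, familial indicators) in all
three tri-states — 3^7 = 2187 scenarios — at three lipid configurations
each, checking that every scenario yields a structurally valid plan and
that the plan-level invariants hold (indeterminate implies
measure-lipids; increase only for the treated; rationale present whenever
anything was recommended). The full cross-product over all fifteen flags
(~14 million records) adds no new decision paths, since the remaining
flags enter the rules independently; the grid size is the package's choice
of an exhaustive-but-economical test.

## Trial statistics

Binary outcomes are compared as differences in proportions, intervention
minus control, on the percentage scale. The confidence interval is the
**unpooled Wald interval**

$$\hat d \pm z_{1-\alpha/2}\sqrt{\frac{\hat p_1(1-\hat p_1)}{n_1}
  + \frac{\hat p_2(1-\hat p_2)}{n_2}},$$

and the test is the 2×2 **Pearson chi-square without continuity
correction** (equivalently, the squared pooled-variance z statistic — a
property the suite checks on random tables). This exact combination
reproduces, to the printed two decimals, every checkable published
interval for this design; that empirical match is the reason it is the
default and only method. Known properties come with it: the Wald interval
undercovers at very small n or extreme proportions, and with 0 or n events
in both arms it degenerates to zero width — degenerate results carry a
flag rather than being silently replaced by a different interval, because
the method actually matched is the method reported.

The analysis is **intention to treat**: denominators are all randomized
participants per arm, numerators are responders reporting the event, so
non-responders count as event-free. Point differences are reported at full
precision by default; `display = "paper"` reproduces the common reporting
convention in which the printed difference is the difference of the
one-decimal rounded percentages (e.g. 2.7 − 4.1 = −1.4 where the raw
difference is −1.32). Both behaviours are real; the default is the honest
one and the other is labelled.

Continuous outcomes use Welch's unequal-variance *t* (via `stats::t.test`
on raw values; a closed-form summary-statistic variant exists for printed
tables). Missing values are excluded, never imputed. Note that published
mean contrasts are generally *not* recoverable from rounded summary
statistics: the rounded weight summaries (77.0 ± 17.2 vs 77.0 ± 16.74)
give a difference of exactly 0 with half-width 1.54, whereas unrounded
means evidently produced the printed 0.03 (−1.51, 1.57). The package
therefore anchors its continuous-outcome machinery to `t.test` agreement
and synthetic data, not to printed values.

**Power.** `two_proportion_power()` implements the two-proportion z-test
power with the pooled-proportion standard error under the null and the
unpooled one under the alternative,

$$\text{power} = \Phi\!\left(\frac{|\Delta| - z_{1-\alpha/2}\,SE_0}{SE_1}\right)
 + \Phi\!\left(\frac{-|\Delta| - z_{1-\alpha/2}\,SE_0}{SE_1}\right),$$

with the far tail included so the null case returns the type-I error rate
exactly. The pooled-null form was chosen over the fully unpooled
approximation (also available as `method = "unpooled"`) because it is what
the z test itself does, and because its integer inverse reproduces the
classical planning answer for this design — 1969 per group, 3938 total,
for 90% power to detect 5% versus 7.5% at two-sided α = 0.05.
`required_n_per_group()` inverts the power function by integer search from
a closed-form start, so the round trip (power at n reaches the target,
power at n − 1 does not) holds by construction and is property-tested.
Both formulas are validated against simulated rejection rates of the
chi-square test itself.

## The synthetic cohort generator

`cohort_spec()`/`generate_baseline()` draw participant records with the
published cohort's marginal structure: each flag Bernoulli at its overall
prevalence (44% male, 66% high-cholesterol diagnosis, 12% diabetes, 27% on
treatment, ...), continuous fields from truncated normals (age 56 ± 12
years on 18–100; weight 77 ± 17 kg; height 170 ± 9.4 cm; recent total
cholesterol 5.6 ± 1.25 mmol/L, positive support), a ~0.5% chance any
individual flag went unanswered, and per-field lipid reporting rates (57%
for recent total cholesterol, ~26% for the subfractions) reflecting how
incomplete self-reported lipid data are in this setting. Aboriginal
heritage has no published marginal; 2% is adopted as a realistic default.

`outcome_spec()`/`generate_followup()` then draw response at the follow-up
rate (default 93%) and each binary outcome at its arm's probability.
Outcome probabilities are configured **on the intention-to-treat scale**
(expected events over all randomized, exactly as outcome tables report
them); since only responders can report an event, the generator draws
responder events at `p / followup_rate`, so the analysis recovers the
configured rate without attenuation and the generative "true difference"
equals the configured difference. Treatment-change outcomes additionally
respect baseline status — only the untreated can commence, only the
treated can increase, with the same marginal-preserving rescaling by the
arm's treated fraction — so the two are mutually exclusive by
construction. Response latency is a shifted log-normal,
`7 + LogNormal(log 3, 0.75)` weeks: median 10 and floor 7 match the
published summary, and the log-normal tail is a modelling choice (only the
median and range were reported; σ = 0.75 puts the maximum of ~2000 draws
in the reported low-40s).

What the generator deliberately does **not** emulate: correlation between
fields (marginals are all that was published; an optional hook conditions
treatment status on the high-cholesterol diagnosis), the friend/relative
referral network's structure (referral is a per-participant Bernoulli
outcome), arm imbalances in baseline characteristics, and any dependence
of response or outcomes on baseline covariates. Passing tests therefore
show that the *machinery* — generation, randomization, advice,
intention-to-treat accounting, interval construction — is correct at the
published operating point, not that the generator reproduces the joint
distribution of the real cohort. Derived baseline rows (untreated but
indicated; treated but above target) in particular depend on the
reconstructed rule set and the independence assumption, and are verified
against a brute-force re-evaluation oracle rather than against published
counts.

## Randomization and orchestration

Allocation is simple unrestricted 1:1 (an independent fair coin per
participant), a pure function of seed and participant order. Central
real-time randomization without stratification is consistent with
unrestricted allocation, as are the unequal arm sizes such trials end
with; blocked alternatives were not implemented. `run_pipeline()` chains
simulate → randomize → advise → follow up → analyze, derives one sub-seed
per stochastic stage from the master seed, and writes the trial CSV, both
tables, the intervention arm's letters and a manifest; a fixed
configuration reproduces its outputs byte for byte. The analysis stage
reads only arm labels and follow-up columns — never the advice plans or
their baseline inputs — which the suite checks by blanking every
advice-relevant baseline field and asserting an identical outcome table.

## Numerical choices and degenerate inputs

* Chi-square margins are computed in double precision (the margin product
  overflows 32-bit integers around trial sizes of 10^5 per arm); a zero
  margin returns statistic 0, p 1, and a degenerate flag.
* Permutation checks of the chi-square p compare against the permutation
  **mid-p** (half the probability atom at the observed table), which is
  the quantity the continuous chi-square approximation estimates; a
  discrete null's full p exceeds the asymptotic p by up to the atom at
  small n.
* CSV serialisation uses `format(..., digits = 15)`, comma separators,
  UTF-8, a required header, and empty string for missing; round-trips are
  lossless and property-tested, including tri-state missingness.
* Ties: a lipid exactly at an eligibility threshold qualifies (`>=`); a
  lipid exactly at a target is at target (`<=`); BMI exactly 24 and TC
  exactly 9 trigger nothing.
* Test problem sizes are the package's own: the scenario grid at 3^7, the
  coverage study at 2000 replicate trials of the published arm sizes, the
  end-to-end recovery run at 200,000 participants — large enough that each
  check's Monte-Carlo error is far below the effect being verified, small
  enough that the whole suite runs in well under a minute.

## Known limitations

* The shipped guideline thresholds are a reconstruction; conclusions about
  eligibility *rates* in synthetic cohorts reflect that reconstruction
  plus the independence assumption, and should not be read as estimates of
  real-world eligibility.
* The Wald interval and chi-square are asymptotic; for very small trials
  use exact methods from another package.
* The generator cannot (and does not try to) model selection into the
  trial, contamination between arms, or time trends — it exists to make
  every downstream stage testable without access to any real data.
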