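---
title: "Methods: diagnosis, burden metrics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosis, burden metrics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headburden)
```

`headburden` implements the analysis pipeline of a community headache survey
of the HARDSHIP family: participant-level questionnaire records are
validated, diagnosed by a rule-based algorithm, and summarised into symptom,
lost-productive-time, disability and economic burden estimates. Because raw
data from such surveys are rarely deposited, the package also ships a seeded
synthetic cohort generator calibrated to the published marginal
distributions of a large survey of 2,329 adults (18-65 years) in Karnataka,
India, so that every stage of the pipeline can be exercised and tested at
desk scale.

## The hierarchical diagnostic algorithm

Diagnoses are made by algorithm, not by interviewers. The hierarchy is:

1. **Chronic split first.** Participants reporting headache on >= 15
   days/month are identified before any episodic rule set is consulted.
   Among these, acute-medication overuse (days/month at or above a
   class-specific threshold) gives *probable medication-overuse headache*
   (pMOH); the remainder are *other headache on >= 15 days/month*.
2. **Episodic rule sets in strict order**: migraine, tension-type headache
   (TTH), probable migraine, probable TTH. The first fully satisfied rule
   set wins; cases satisfying none are *unclassified*. Screen-negative
   participants are *no_headache*.

The ICHD-II criteria are shipped as a YAML **criteria registry**
(`inst/extdata/ichd2_criteria.yaml`) rather than hard-coded logic, so the
encoding is auditable and swappable: migraine 1.1 (>= 5 lifetime attacks;
4-72 h duration; >= 2 of unilateral / pulsating / moderate-or-severe /
aggravated-by-activity; nausea/vomiting or photophobia + phonophobia) and
TTH 2.x (episode count; 30 min - 7 d; >= 2 of the four inverse pain
features; no nausea and at most one of photophobia/phonophobia). Probable
variants require all but one criterion.

Design choices in the registry, made where the questionnaire or the
classification leaves room:

* **Episode-count proxy.** The questionnaire records lifetime attack count
  only as a ">= 5" indicator. ICHD-II TTH formally requires >= 10 episodes;
  the registry maps that criterion to the same indicator. This can only
  promote borderline TTH cases (5-9 lifetime episodes) into TTH rather than
  probable TTH.
* **Inverse pain features.** TTH's "mild or moderate intensity" is encoded
  as the logical negation of the migraine feature "moderate or severe",
  because the instrument binarises each pain feature; the overlap at
  "moderate" cannot be represented with the recorded fields.
* **Overuse thresholds.** The survey did not print them; the registry uses
  ICHD-II 8.2: >= 15 days/month for simple analgesics, >= 10 for
  combination or specific drugs (class `none` never overuses). They are
  data, hence configurable. ICHD-II's requirement of > 3 months of overuse
  is exposed as an optional registry field, off by default, because the
  survey recorded no overuse duration.
* **Tie rule.** A case missing exactly one migraine criterion and one TTH
  criterion is *probable migraine*, per the stated evaluation order.

`diagnose_cohort()` records every predicate evaluated up to the rule set
that fired in an `audit` column; `explain_diagnosis()` expands it into a
report from which the category can be re-derived by hand. The suite checks
the algorithm against an independent straight-line re-implementation on a
discretized grid of all 1,024 boolean feature combinations crossed with
frequency and medication patterns (15,360 records), asserting that the
categories partition the grid.

## Burden metrics

**Lost productive time.** HALT-style questions record days lost from paid
work and from household chores over the preceding 3 months (each capped at
the 92-day calendar ceiling). The percentage of all productive time lost by
a group is `100 * sum(4 * days lost) / (n * 240)`: the enquiry window is
annualized by 4 and each person is assumed to have 240 working days/year.
The factor 4 is forced by consistency of the published per-quarter means
with the published annual percentages (3.5 days/quarter -> 5.8 %,
13.9 -> 23.2 %). The same 240-day year is applied to household work — a
stated simplification of the original analysis, kept here because there is
no clear basis for another denominator. Scaling a within-group percentage
to the population (`population_time_lost()`) multiplies by the group's
prevalence as a proportion.

**Ictal-state disability.** For migraine, mean time in the ictal (attack)
state as a proportion of all time is `T = (D/24) * (F/365) * 100`, with `D`
the mean attack duration (hours) and `F` the mean headache days/year; one
headache day is equated with one attack, so durations above 24 h are capped
at a full day (with a warning). Per-person disability is `d = T * DW` with
`DW = 0.433`, the GBD2010 disability weight for the migraine ictal state,
and population-level disability is `d * P` with `P` the migraine
prevalence. `migraine_disability()` defaults `P` to the crude sample
prevalence (diagnosed count / cohort size); the original analysis used the
crude prevalence for disability but the age-standardised prevalence for
population lost time, an inconsistency that the explicit `prevalence`
argument surfaces rather than resolves.

All summaries keep full precision internally; rounding to one decimal place
happens only in `render_tables()`.

## Economics

Expenditure on headache care over 3 months and willingness to pay (WTP) for
effective treatment are summarised over the four published INR bands
(<= 100, 101-500, 501-1,000, > 1,000; boundary values belong to the lower
band, matching the printed labels). Expenditure as a share of quarterly
income multiplies reported monthly income by three; zero expenditure is 0 %
regardless of income, while a positive expenditure with missing or zero
income yields a missing share that is excluded from moments and counted.
The WTP/expenditure ratio is reported as the **mean of per-person ratios**
(the published statistic; the ratio of means is also exposed because the
two differ markedly on skewed data). Zero-expenditure participants have no
finite ratio and are excluded by default and counted; a floor-at-1-INR
policy is available, since the source is silent on the handling.

## Statistical reporting

Group comparisons use the tests named in the original analysis: chi-squared
(without continuity correction), Student's t (Welch's unequal-variance
form, as the original does not specify), and one-way ANOVA; Pearson
correlation links annual headache frequency with annualized lost time.
Degenerate inputs (zero variance) give flagged results rather than
exceptions. Proportions carry Wilson score 95 % intervals by default (the
interval `prop.test()` computes without continuity correction); a Wald
option exists for strict mimicry of normal-approximation reporting. No
multiple-testing correction is applied, matching the original analysis —
a deliberate reproduction choice, not a recommendation. Significance stars
follow the published convention (`***` p < 0.001, `**` p < 0.01, `*`
p < 0.05).

## The synthetic cohort generator

`generate_cohort()` emulates the *marginal* statistical structure of the
published sample; its defaults are the study conditions:

* 2,329 participants; sex split 1,141/1,188, habitation 1,226 urban / 1,103
  rural; age truncated-normal 38 (SD 12.7) on 18-65.
* Headache in the preceding year with sex-specific probabilities
  (621/1,141 male, 867/1,188 female; overall 63.9 %).
* Type mixture conditional on headache: 597/811/28/40/12 out of 1,488
  (migraine / TTH / pMOH / other >= 15 d/m / unclassified).
* Frequency: episodic types draw headache days/year from a negative
  binomial matched to the published mean/SD (28 +/- 27 migraine, 17 +/- 20
  TTH), clamped to [1, 179] so episodic cases stay below the chronic
  threshold (the clamp moves the mean by < 0.01 days); chronic types draw
  days/month from a truncated normal on [15, 30] whose location is solved
  numerically so the truncated mean matches 226/12 (pMOH) or 259/12
  (other).
* Attack duration: truncated lognormal with the coefficient of variation of
  the published 13.1 +/- 16.9 h (migraine, on [4, 72] so the 4-72 h
  criterion holds) and location again solved for the truncated mean;
  durations for the other types are plausible values, not published ones.
* Intensity: the published category counts per type.
* Diagnostic features are drawn per type and then minimally adjusted so the
  record satisfies its latent type's rule set (e.g. a migraine record that
  drew fewer than two pain features has unilateral and pulsating set); pMOH
  records draw medication days at or above the class threshold, chronic
  non-overusers strictly below. Unclassified records have sub-30-minute
  attacks and no attack-count indicator, failing two criteria of each
  episodic rule set. Diagnosis therefore recovers the latent label exactly
  with default settings; `boundary_noise` optionally knocks out the
  attack-count indicator to demote episodic cases to their probable
  variants.
* Lost time: independent zero-inflated exponentials for paid and household
  days (means and zero-probabilities per type chosen to reproduce the
  published means and the "most medians are zero" pattern), rounded to
  whole days and capped at 92. Multiplicative shifts (female x1.2, rural
  x1.2, normalized so type-level means are preserved) echo the published
  female > male and rural > urban gradients, and a frequency-linked
  multiplier induces the published positive frequency-loss correlation.
* Economics: consultation probabilities and level distributions, and
  expenditure/WTP band probabilities, follow the published tables, with
  uniform within-band amounts and a lognormal tail above 1,000 INR. Income
  is lognormal (median 6,000 INR/month) with 5 % missing.

The published tables report both headache *days* and, for migraine,
*attacks* per month; which one the ">= 3 per month" threshold counts is
ambiguous in the source. The generator emits both fields (equal by
default — one attack per headache day) and `symptom_summary(ge3_basis =)`
makes the choice explicit instead of resolving it.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: the multistage cluster sampling design and
any intra-cluster correlation; recall error; correlations between economic
variables and severity beyond the type level; seasonal effects; and any
joint structure of the unclassified cases, which the source never
describes. Calibration checks are against the published *means* (and the
zero medians); higher moments of the skewed lost-time and expenditure
distributions are not targets.

All randomness flows from the single integer seed in the spec
(`withr::with_seed`), so cohorts are byte-for-byte reproducible after
serialization and the caller's RNG state is untouched.

## Numerical and testing choices

* Truncated-distribution locations are solved with `uniroot` to 1e-10;
  degenerate far-outside-window cases fall back to the near boundary.
* Stochastic calibration tests use fixed seeds and 3-standard-error bands,
  with the SE built from the published SD and the realized category size;
  the suite exercises cohorts of n = 2,329 (the study size) and n = 10,000
  (tighter calibration check), which keeps the full suite around ten
  seconds.
* Exactness tests compare every summary against naive loop-based
  re-computations on small cohorts (n <= 50), and the diagnostic algorithm
  against an independent rule-table re-implementation on the full feature
  grid.
* Empty groups yield `NA` moments with an explicit flag (never silent
  zeros), and validation reports every violating row and field rather than
  stopping at the first.

## Known limitations

* The criteria registry encodes ICHD-II as far as the questionnaire fields
  allow; aura subtyping, secondary-headache screening and ICHD-3 are out of
  scope.
* One feature set per participant: the "most bothersome headache" selection
  is assumed to have happened upstream, as in the source instrument.
* Whether paid and household lost days may refer to the same calendar day
  is unspecified in the source; no overlap constraint is imposed, so total
  lost time can exceed 92 days/quarter in principle (each component is
  capped separately).
* WTP is treated as a unitless reported amount; its elicitation period is
  not stated in the source.
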