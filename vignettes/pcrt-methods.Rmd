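---
title: "Methods: questionnaire scoring, NOD triage, and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: questionnaire scoring, NOD triage, and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(pcrt)
```

## The instrument and its two pathways

`pcrt` models a patient-completed screening questionnaire for a GI
outpatient population that drives two independent triage pathways:

1. **Familial risk.** Personal and first-degree family cancer history is
   converted into an integer point score; a total at or above the referral
   threshold (default 3) indicates referral to genetic counseling.
2. **New-onset diabetes (NOD).** Self-reported weight change, fasting
   glucose change, and timing of the glycemic change are combined into a
   questionnaire-level ENDPAC-criteria flag; respondents who meet it (and
   have no pre-existing pancreatic cancer diagnosis) are candidates for
   direct high-risk clinic enrollment.

The pathways are evaluated independently: a respondent can trigger both,
either, or neither, and toggling answers in one never changes the other
(this independence is property-tested).

## The scoring rule

For each cancer event the score adds `base(type)`, plus `mod(type)` when
the event was diagnosed at or before age 50, plus a flat ancestry bonus of
2 applied once when either parent is of Ashkenazi descent:

| type | base | age modifier |
|---|---|---|
| pancreatic | 3 | 0 |
| ovarian | 3 | 0 |
| thyroid | 2 | 0 |
| breast | 1 | 2 |
| colorectal / prostate / melanoma | 1 | 0 |
| other | 0 | 0 |

**Where the table comes from.** The instrument's published description
prints only two example rules (pancreatic = 3; breast = 1, +2 under 50)
plus six fully worked scores (8, 6, 6, 6, 1, 3). The remaining values are
the completion of those constraints: brute-force enumeration over 0..4
(reproduced in the test suite) shows colorectal = 1, prostate = 1 and
ancestry = 2 are forced, while thyroid + ovarian is only pinned to 5. We
ship thyroid = 2 / ovarian = 3, placing ovarian on par with pancreatic as
in NCCN-style referral criteria; any other completion can be supplied as a
JSON config (`load_point_table()`). Two further choices the worked scores
force: ovarian carries *no* age modifier (the mother-ovarian-under-50 case
only works if ovarian contributes 3 flat), and the ancestry bonus does not
double when both parents qualify (the both-parents case sums to 6 only
with a flat 2).

**Age cutoff.** The questionnaire item asks about diagnosis "before or at
the age of 50" while the example prose says "under the age of 50"; the flag
follows the questionnaire wording (`dx_at_or_before_50`) because that is
what respondents answered. An unknown diagnosis age scores base points only
— the conservative reading of the missing-data convention.

## Missing data

Tri-state items (`yes`/`no`/`unknown`) are never collapsed: an
unanswered glucose item makes a respondent *not assessable* rather than
negative, and blank CSV cells deserialize to `"unknown"`. This matters
quantitatively: in the published funnel roughly a third of NOD-section
completers could not answer the glucose item, so coercing unknown to "no"
would silently move 128 respondents from "not assessable" to
"does not meet".

## ENDPAC criteria

`percent_weight_change(current, previous)` is
`100·(current−previous)/previous`, rounded half away from zero to an
integer percent, loss negative (both published cases, −14% and −4%,
reproduce exactly; base R's banker's rounding would not reproduce a .5
case, hence the explicit rule). Any self-reported loss qualifies by
default, because the published flagged cases include a 4% loss; a
`min_loss_pct` knob exists for stricter deployments (a loss qualifies when
`weight_change_pct < 0` and `|weight_change_pct| >= min_loss_pct`).
Verdict precedence: pre-existing pancreatic cancer → `excluded_prior_pc`
(dominates everything, since such a patient still receives familial
scoring but has nothing to gain from early-detection enrollment); then
assessability; then the criteria test. "Around the age of 50" is a
questionnaire item, not a derivation from age fields — the instrument asks
it directly.

The full published three-variable ENDPAC point model (bins over age at
glycemic onset, weight change, glucose change) is supported structurally
(`endpac_point_model()`, `endpac_score()`) but ships with **no default
parameterization**: the source instrument never prints the bins, and
importing them from elsewhere would smuggle numbers the package's tests
could not anchor. Supplying the published bins as JSON config is a
one-liner for users who have them.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` draws independent respondents with configurable
prevalences. The defaults are the stated world of the source cohort:
n = 453, 55.4% female, age ~ N(63, 13) clamped to 18–95 (median ≈ 65),
76.8% NOD-section completion, 36.8% of completers glucose-unknown, 12.5%
of those additionally weight-unknown (nested — see below), pre-existing
pancreatic cancer 6/453, prior genetic testing 18/453, ~5% Ashkenazi
ancestry, ~23% diabetes/glucose intolerance, ~7% current smokers. Event
probabilities per relative were chosen once to give a plausible GI-clinic
score distribution (~19% personal cancer history; median score ~1); they
are knobs, not claims.

Randomness uses one top-level seed with per-respondent substreams keyed by
`(seed, counter)`, so cohorts are bit-identical across runs and a cohort of
n = 10 is a prefix of the same-seed cohort of n = 40 — inserting a
respondent never perturbs the others, which keeps property tests stable.

The generator does **not** emulate: correlation between family history and
NOD items, within-family correlation of cancer types, secular weight
trends, second-degree relatives, or genetic test results (pathogenic
variants are out of scope; gene names appear only as fixture labels). A
green test therefore establishes arithmetic and funnel correctness, not
epidemiological realism.

`fixture_cohort()` is deterministic and exact: 453 records whose funnel
under default triage reproduces every published count (117 ≥ threshold;
18 prior testing, 15 of them high-risk; 6 pre-existing pancreatic cancer;
348 NOD-completed; 128 glucose-unknown ⊇ 16 weight-unknown; 220
assessable; 4 ENDPAC-met), with the six published worked-example patients
embedded verbatim. Two source inconsistencies are resolved as follows and
flagged rather than hidden: (a) 348 − 128 − 16 ≠ 220, so the 16
weight-unknown respondents are nested inside the glucose-unknown stratum,
which is the only reading that honors 220; (b) the published demographic
table's groups sum to 435, not 453 — the fixture scores everyone, so its
low-risk group has 336 members and no phantom "unscored" stratum is
fabricated. Of the four ENDPAC-met respondents, one overlaps the high-risk
117 (the score-3 sibling-pancreatic patient) and three score below
threshold, consistent with the published patient table.

## Statistical conventions

Group comparisons (score < threshold vs ≥ threshold) use chi-square
without Yates continuity correction for binary frequencies, Fisher's exact
test for the sparse ethnicity table, and Mann–Whitney (normal
approximation with tie correction, `wilcox.test(exact = FALSE)`) for age —
reported as median (IQR), not mean. The continuity-correction default is a
genuine unknown of the original analysis (R 4.0.2 is stated, options are
not); uncorrected lands on the printed Female-row p (0.4797 ≈ 0.48) and a
`correct` switch exists. The Ashkenazi row keeps chi-square, as printed,
although its expected counts are small enough that Fisher would be
defensible; this is implemented as printed and noted here. No
multiple-testing adjustment is applied, matching the unadjusted published
table. Percentages are printed to one decimal with half-away-from-zero
rounding, which reproduces all eight published funnel percentages from
their integer counts.

## Numerical and degenerate-input choices

* Rounding: half away from zero everywhere a printed number is mimicked
  (weight-change percent, one-decimal percentages).
* `format_percent` with zero denominator and `percent_weight_change` with
  non-positive weights are domain errors, not NaN.
* A cohort with only one non-empty risk group produces a degenerate summary
  table with tests omitted (`p = NA`) rather than an error.
* Validation reports problems (severity `error`/`warning`) instead of
  raising; only cohort-level duplicate ids raise, since no per-record
  report can represent them.
* Sibling multiplicity is uncapped: every affected sibling scores
  independently (the source cohort's maximum observed score was 13).

## Known limitations

The schema is reconstructed from the published items and result tables;
the complete deployed instrument (supplementary material) may include
fields not modeled here. The default point table is guaranteed only on the
cancer types the worked examples constrain. Real-cohort outcome rates that
depend on actual genetic testing (pathogenic-variant yield, VUS rate) are
out of reproduction scope and appear only as configurable simulation
labels. Weights are pounds throughout; no unit conversion.
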