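---
title: "Methods: episode construction, treatment patterns and the off-label audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episode construction, treatment patterns and the off-label audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldxdur)
```

## The analysis

`ldxdur` implements a drug-utilization analysis for lisdexamfetamine (LDX)
prescribing in ADHD, of the kind run on European national registries,
EMR databases and pharmacy panels. From three longitudinal event tables —
patients, prescription issues/dispensings, diagnoses — it derives, per
patient:

* **Coverage intervals.** Each prescription is assumed to supply medication
  for a *prescription period*: the recorded days of supply if present,
  otherwise `quantity × strength / instructed daily dose`, otherwise a
  configurable default (30 days). Intervals are closed–open `[start, end)`
  in whole-day units, with ISO-8601 calendar dates throughout.
* **Treatment episodes.** Per patient and drug, coverage intervals whose
  next prescription is issued within the 30-day grace period of the running
  supply end are merged; a longer gap closes the episode. The same 30-day
  parameter (`gap_days`) drives episode building, discontinuation and
  switching, since all three definitions use the same window.
* **Exposure and average daily dose.** Duration of exposure is the sum of
  episode spans (first issue to final supply end within each episode); the
  first-to-last span across gaps is also emitted (`followup_span_days`)
  because the "duration of exposure" reading is genuinely ambiguous — the
  episode sum is the headline since minimum durations of a day or two only
  arise at per-coverage granularity. The average daily dose (ADD) is total
  milligrams dispensed over total *covered* days, so treatment gaps cannot
  dilute the dose; by the same token the ADD cannot see gaps, and
  underestimates nothing but also never averages over off-drug time.
  Cohort mean-dose statistics pool only patients with ADD at or below the
  70 mg/day label cap; the above-cap share is reported separately and feeds
  the off-label audit.
* **Patterns.** *Discontinued*: an LDX episode end followed by no LDX and no
  other-ADHD-drug prescription within 30 days, with at least 30 days of
  observation remaining (otherwise the end is *censored*). *Switched to
  LDX*: an LDX issue within 30 days after the end of another ADHD drug's
  prescription period. *Switched from LDX*: the mirror image. Switch flags
  are not exclusive; at a single episode end, switch evidence and
  discontinuation exclude each other.
* **Off-label audit.** Declarative per-country rules: no ADHD diagnosis
  recorded strictly before the first LDX prescription; no prior
  methylphenidate (MPH), evaluable only with ≥365 days of enrolment
  history; age below 6 at any prescription; ADD strictly above 70 mg/day;
  and adult (≥19) use outside the country's approval status.

## Conventions the source definitions leave open

Several choices are not fixed by the verbal definitions; the package fixes
them once, exposes them as parameters, and tests the boundaries.

**Window boundary.** "Within 30 days following the end" is read inclusively:
`issue − end ∈ [0, 30]`. A gap of exactly 30 days therefore merges an
episode and detects a switch; 31 days does not. The alternative
half-open reading is available as `boundary = "exclusive"` and is covered by
boundary tests at exactly 30 and 31 days.

**Overlapping refills.** A refill issued before the previous supply runs out
is *stockpiled*: its coverage starts when the running supply ends, so
dispensed days are conserved through merging (mg and covered days are
invariants of episode construction, and the suite checks them). The
alternative, truncating the earlier interval at the next issue, is available
as `overlap = "truncate"` and discards the overlapped supply. Conservation
is the defensible default for dispensing data; prescription-period ends used
to anchor switching are the stockpile-adjusted ends, for coherence with the
episode model.

**Censoring.** How patients whose last supply ends near the observation end
were handled in the original analyses is not stated. Here an episode end
with fewer than `gap_days` days of remaining observation is *censored*, not
discontinued; the follow-up-blind count (`discontinued_naive`) is also
reported for comparability.

**Re-initiation.** Discontinuation is flagged at every qualifying episode
end, and the patient-level headline is "ever discontinued". A patient can
therefore discontinue, re-initiate, and later switch; all flags stand. This
inflates discontinuation relative to a last-episode-only reading — on the
synthetic cohorts most refill streams eventually show a >30-day gap — and
is the main reason synthetic discontinuation proportions sit near the top
of, or above, the ranges reported for real registries.

**Adult continuation.** "Treatment continued from adolescence into
adulthood" is operationalized as: the LDX episode (30-day grace rule)
containing the adult prescription began at age ≤ 18. Because episodes are
maximal, an episode chain with gaps ≤ 30 days *is* a single episode, so no
separate chain rule is needed. Ages are year-granular (event year minus
birth year), matching what registries typically expose; exact birth dates
are never assumed. Band membership (0–5, 6–12, 13–18, 19–25, >25) uses age
at first LDX prescription for demographics and age at each prescription for
the audit.

**Dose criterion.** "A prescribed dosage exceeding 70 mg/day" can be read
per-patient (average) or per-prescription. Both are computed
(`dose_exceeds_cap`, `any_rx_dose_exceeds_cap`); the average-dose variant is
the headline, consistent with mean-dose reporting being restricted to
≤70 mg/day patients.

**Switzerland and Denmark.** The Swiss adult approval (adults up to 55) is
dated 2014 with no published month; the fixture uses the Swiss launch month
(August 2014) as the effective date. Denmark's adult off-label proportion is
computed but flagged not-evaluable in comparison output
(`adult_off_label_reportable: false`), since adult use there straddles the
2015 label extension and cannot be attributed from counts alone.

**Not-evaluable propagation.** Flags that cannot be evaluated (sources
without diagnoses, missing birth years, short enrolment histories) are `NA`
and are excluded from both numerator and denominator of the corresponding
proportion; every reported percentage carries its denominator. `NA` never
contributes to `any_off_label`.

**Degenerate inputs.** Empty cohorts produce an explicit all-zero summary
with undefined proportions; records with no basis for an interval length or
dose are returned as record-level rejections, never silently dropped; a
single-patient cohort reports an SD of 0 rather than `NA`.

## The synthetic cohort generator

Real registry extracts are not redistributable, so `simulate_cohort()`
stands in for them. It emulates the *structure* the analysis assumes:
per-country launch dates and observation windows (the eight shipped
`country_config` fixtures), age/sex mixes and diagnosis-recording
completeness in realistic ranges, refill behaviour as a two-component
mixture (on-time refills within ±5 days of the supply end, with
probability 0.85; otherwise a lognormal late tail, `meanlog = log 45`,
`sdlog = 0.5`, whose mass above 30 days produces episode breaks), per-refill
discontinuation (0.08) and switch (0.03) hazards giving on the order of
7–9 prescriptions per patient, a dose mix over 20–70 mg/day with 5% mass at
100 mg/day, and source-specific missingness (Swiss pharmacy panels carry no
diagnoses; the self-dispensing panel no ages or durations). Defaults were
chosen once as plausible study conditions; the generator is deliberately
*not* calibrated to any country's published results, and no generator
parameter doubles as a test tolerance.

Because stops, switches and late refills are generated rather than
inferred, the generator knows each patient's true event labels and returns
them (`truth`). The strongest end-to-end check in the suite is exact
recovery: on a 5000-patient cohort the classifier must reproduce every
generated discontinuation, switch-to, switch-from and censoring label with
zero discordance. Passing this shows the pipeline implements the 30-day
definitions exactly as specified — it does not show that the definitions
capture real prescribing behaviour, and the generator omits features of
real data (dose titration, seasonal refill patterns, transfers between
providers, EMR history truncation) that would blur real-world estimates.

## Verification strategy and problem sizes

* Classifier–oracle equivalence: an enumerated grid of 2–3-prescription
  sequences with gaps spanning the grace boundary, plus 10,000 random
  sequences of up to 6 prescriptions over two drugs with gaps 0–60 days,
  all compared against quadratic pairwise-scan and sequential-loop oracles
  written independently of the vectorised implementation.
* Property suites: conservation of mg and covered days through merging;
  episode counts non-increasing in `gap_days` over {7, 14, 30, 60, 90};
  idempotence of episode construction; ADD invariance under prescription
  splitting; adult off-label counts non-increasing as the approval date
  moves earlier; purely declarative rule evaluation (changing only the
  approval date changes only the adult flags).
* Marginal recovery: with a prior-MPH probability of 0.8, the no-prior-MPH
  flag rate among evaluable patients must fall inside a 99% binomial
  interval around 0.20 at n = 5000.
* Dual-path aggregation: cohort summaries are recomputed from raw events by
  an independent brute-force path on a matrix of simulated cohorts
  (Sweden, Norway, Switzerland, United Kingdom; 400–800 patients each) and
  must agree to numerical precision.

Simulation sizes (5000 patients for the recovery and marginal checks,
400–1000 elsewhere) keep the full suite in the low minutes on a single CPU
while leaving binomial tolerances tight.

## Limitations

The package audits *recorded* prescribing: it cannot distinguish
prescriptions written from dispensings filled (the distinction lives in
`SourceProfile` descriptions only), cannot see medication actually taken,
and inherits every completeness limitation of its inputs. The ADD ignores
treatment gaps by construction. Off-label flags are operational definitions,
not clinical judgments — prescribing that follows national guidelines can
still be flagged when the label disagrees. No adherence indices (MPR/PDC)
or time-to-event analyses are computed.
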