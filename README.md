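# ldxdur

Drug-utilization analysis of lisdexamfetamine (LDX) prescribing in ADHD,
built for pharmacoepidemiologists working with longitudinal prescription
data (national registries, EMR extracts, pharmacy panels) or needing a
fully testable stand-in for them.

From three delimited event tables — patients, prescriptions, diagnoses —
the package:

* builds **coverage intervals** per prescription (recorded days of supply,
  else `quantity × strength / daily dose`, else a 30-day default) and
  merges them into **treatment episodes** with a 30-day grace period,
  conserving dispensed supply when refills overlap (stockpiling);
* computes **exposure duration** (sum of episode spans), repeat-user
  status, and the **average daily dose** ADD = total mg dispensed / total
  covered days, with the 70 mg/day label cap;
* classifies **treatment patterns** with the shared 30-day window:
  *discontinued* — an episode end followed by no LDX and no other ADHD
  drug within 30 days, with ≥30 days of observation left (else
  *censored*); *switched to/from LDX* — a prescription of the other drug
  class within 30 days after a prescription-period end;
* audits every patient against **declarative country label rules**
  (recorded ADHD diagnosis before first LDX; prior methylphenidate, given
  ≥365 days of history; minimum age 6; ADD ≤ 70 mg/day; adult use under
  each country's approval status, with a continuation-from-adolescence
  exemption). Fixtures ship for Denmark, Finland, Germany, Norway, Spain,
  Sweden, Switzerland and the United Kingdom over their 2013–2017
  observation windows;
* aggregates everything into **cohort summaries** with every percentage's
  denominator alongside it, plus a **synthetic cohort generator** whose
  generated event labels are known exactly — the pipeline is required to
  recover them with zero discordance.

## Worked example

```r
library(ldxdur)

co  <- simulate_cohort(simulation_config(n_patients = 400, seed = 11))
res <- dua(co$patients, co$prescriptions, co$diagnoses, co$country_config)
summary(res)
```

```
Cohort summary — Sweden (n = 400 patients, 2806 LDX prescriptions)
  Male:                   271/400 (67.8%)
  Documented ADHD dx:     318/400 (79.5%)
  Age bands 0-5/6-12/13-18/19-25/>25: 1/116/139/41/103 (denom 400)
  Repeat users:           351 (87.8%)
  Rx per patient:         mean (SD) 7.0 (5.7); median 5 (1; 31)
  Exposure (days):        mean (SD) 222.2 (182.2); median 169.5 (30; 955)
  Avg daily dose (mg/d):  mean (SD) 45.4 (14.4); median 50 (20; 70)  [<= cap, n = 373]
  ADD above cap:          27/400 (6.8%)
  Discontinued:           295 (73.8%)  [naive 342; censored 85]
  Switched to LDX:        159 (39.8%)
  Switched from LDX:      88 (22.0%)
  No prior diagnosis:     82/400 (20.5%)
  No prior MPH:           68/380 (17.9%)
  Under minimum age:      1/400 (0.2%)
  Adult off-label:        66/400 (16.5%)
  Any off-label:          190 (47.5%)
```

Reading it: 351 of 400 synthetic patients received more than one LDX
prescription; mean exposure is 222 days of episode time; the mean average
daily dose among the 373 patients at or below the 70 mg/day cap is
45.4 mg/day, and 27 patients exceed the cap (one of the off-label
criteria). "Discontinued" is *ever* discontinued at any episode end with
adequate follow-up — the follow-up-blind count (342) and censored count
(85) are printed beside it. Each off-label line shows its evaluable
denominator: 20 patients lack the 365-day history needed to judge prior
MPH use, so that line is out of 380.

`res$patient_summary` holds the per-patient table behind these numbers;
`plot(res)` draws the pattern proportions and the dose distribution.
File-based use mirrors this: `write_cohort()` / `read_cohort()` for the
event tables, `run_pipeline(input_dir, out_dir, "sweden")` for an
end-to-end run emitting per-patient, cohort-summary, rejection-log and
run-log files (byte-identical on identical inputs). A thin CLI wrapper
lives in `inst/cli/ldxdur`.

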