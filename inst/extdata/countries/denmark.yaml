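country: Denmark
launch_date: 2013-03-01
adult_approval_date: 2015-01-01
observation_start: 2013-03-01
observation_end: 2017-01-01
min_label_age: 6
max_daily_dose_mg: 70
requires_prior_mph: true
requires_recorded_diagnosis: true
mph_lookback_min_enrolment_days: 365
# Pre-2015 adult use predates the label extension; the source data cannot
# attribute adult use before/after approval, so the adult criterion is
# reported as not evaluable in paper-comparison output.
adult_off_label_reportable: false
sources:
- source_id: dk_registry
  records_diagnoses: true
  records_ages: true
  records_durations: true
  description: National registry; dispensed prescriptions, near-complete coverage
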