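country: Finland
launch_date: 2014-09-01
adult_approval_date: ~
observation_start: 2014-09-01
observation_end: 2017-01-01
min_label_age: 6
max_daily_dose_mg: 70
requires_prior_mph: true
requires_recorded_diagnosis: true
mph_lookback_min_enrolment_days: 365
adult_off_label_reportable: true
sources:
- source_id: fi_registry
  records_diagnoses: true
  records_ages: true
  records_durations: true
  description: National registry; dispensed prescriptions, near-complete coverage
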