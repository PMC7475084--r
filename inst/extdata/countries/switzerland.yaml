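country: Switzerland
launch_date: 2014-08-01
# Adult approval effective 2014 (month not published); aligned with launch.
adult_approval_date: 2014-08-01
adult_age_cap: 55
observation_start: 2014-08-01
observation_end: 2018-01-01
min_label_age: 6
max_daily_dose_mg: 70
requires_prior_mph: true
# Swiss pharmacy panels carry no diagnosis records at all.
requires_recorded_diagnosis: false
mph_lookback_min_enrolment_days: 365
adult_off_label_reportable: true
sources:
- source_id: ch_ppp
  records_diagnoses: false
  records_ages: true
  records_durations: true
  description: Pharmacy prescription panel; retail dispensings, no diagnoses
- source_id: ch_sdpp
  records_diagnoses: false
  records_ages: false
  records_durations: false
  description: Self-dispensing prescription panel; no diagnoses, ages or durations
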