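country: Germany
launch_date: 2013-06-01
adult_approval_date: ~
observation_start: 2013-06-01
observation_end: 2018-01-01
min_label_age: 6
max_daily_dose_mg: 70
requires_prior_mph: true
requires_recorded_diagnosis: true
mph_lookback_min_enrolment_days: 365
adult_off_label_reportable: true
sources:
- source_id: de_da_pp
  records_diagnoses: true
  records_ages: true
  records_durations: true
  description: EMR disease-analyzer paediatrician panel; prescriptions written, not fills
- source_id: de_da_npp
  records_diagnoses: true
  records_ages: true
  records_durations: true
  description: EMR disease-analyzer neurologist/psychiatrist panel; prescriptions written, not fills
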