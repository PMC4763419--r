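format: trauma24-model/1
name: generating_truth
provenance: >-
  Synthetic data-generating model: 4-knot restricted cubic spline of systolic
  blood pressure plus linear Glasgow coma scale. Risk falls ~0.045 log-odds
  per mmHg below 100 mmHg and plateaus above 135 mmHg; each coma-scale point
  lowers the log-odds by 0.25. Intercept calibrated so the default cohort
  spec yields ~6.8 % 24-h mortality.
shrinkage_factor: 1.0
terms:
- variable: sbp
  form: spline
  knots: [100.0, 112.0, 120.0, 135.0]
  n_knots: 4
- variable: gcs
  form: linear
coefficients:
  intercept: 4.8502
  sbp_sbf1: -0.045
  sbp_sbf2: -0.011484375
  sbp_sbf3: 0.14355469
  gcs: -0.25
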