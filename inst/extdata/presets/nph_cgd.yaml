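description: >
  Non-proportional-hazards working model: treatment coefficient switches
  from -1.117 to +0.750 at a 40-week knot (early benefit, later harm), sex
  at its fitted value -0.402 in both intervals. One trial of 130 subjects.
model:
  lambda_a: 0.0158
  lambda_b: 0.0158
  beta_a: [-1.117, 0.094, -0.402, 0.475]
  beta_b: [0.750, 0.094, -0.402, 0.475]
  t1: 40
trial:
  n_subjects: 130
  prevalence: 0.5
censoring:
  random_rate: 0.001
  accrual_window: 20
  study_end: 120
study:
  hypothesis: alternative
  t_star: [40]
  n_reps: 2000
  seed: 20260402
  methods:
    - name: parametric_full
      type: parametric
      covariates: [treatment, inherit, sex, treatment_inherit]
      knot: 40
    - name: parametric_knot50
      type: parametric
      covariates: [treatment, inherit, sex, treatment_inherit]
      knot: 50
    - name: nonparametric
      type: nonparametric
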