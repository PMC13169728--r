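description: >
  Power at t* = 40 weeks as the fitted knot varies from 15 to 40 weeks while
  data come from the non-proportional-hazards working model with true knot
  40; nonparametric reference carried along; 130 subjects per trial.
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
  seed: 20260407
  methods:
    - name: parametric_full
      type: parametric
      covariates: [treatment, inherit, sex, treatment_inherit]
      knot: 40
    - name: nonparametric
      type: nonparametric
  sweep:
    kind: knot
    grid: {from: 15, to: 40, by: 5}
    t_star: 40
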