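description: >
  Power across truncation times 1..120 weeks under the non-proportional-
  hazards working model (true knot 40 weeks): correctly specified parametric
  fit (knot 40), knot misspecified at 50 weeks, and nonparametric; 130
  subjects per trial.
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
  t_star: {from: 1, to: 120, by: 1}
  n_reps: 2000
  seed: 20260406
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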