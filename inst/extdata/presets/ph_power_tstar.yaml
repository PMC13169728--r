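description: >
  Power of all three estimators across truncation times 1..120 weeks under
  the proportional-hazards working model (sex coefficient -1), 100 subjects
  per trial.
model:
  lambda_a: 0.0158
  lambda_b: 0.0158
  beta_a: [-1.117, 0.094, -1.0, 0.475]
  beta_b: [-1.117, 0.094, -1.0, 0.475]
  t1: 0
trial:
  n_subjects: 100
  prevalence: 0.5
censoring:
  random_rate: 0.001
  accrual_window: 20
  study_end: 120
study:
  hypothesis: alternative
  t_star: {from: 1, to: 120, by: 1}
  n_reps: 2000
  seed: 20260403
  methods:
    - name: parametric_full
      type: parametric
      covariates: [treatment, inherit, sex, treatment_inherit]
      knot: 0
    - name: parametric_nosex
      type: parametric
      covariates: [treatment, inherit, treatment_inherit]
      knot: 0
    - name: nonparametric
      type: nonparametric
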