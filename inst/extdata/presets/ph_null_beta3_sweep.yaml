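description: >
  Type I error of the sex-omitting parametric estimator at t* = 100 weeks as
  the generating sex coefficient varies from -2 to 2 under the null
  proportional-hazards generator, 100 subjects per trial.
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
  hypothesis: "null"
  t_star: [100]
  n_reps: 2000
  seed: 20260405
  methods:
    - name: parametric_nosex
      type: parametric
      covariates: [treatment, inherit, treatment_inherit]
      knot: 0
    - name: nonparametric
      type: nonparametric
  sweep:
    kind: beta3
    grid: {from: -2, to: 2, by: 0.5}
    t_star: 100
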