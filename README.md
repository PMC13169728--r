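# rmstcomb

Combined treatment effects via restricted mean survival time.

## The problem

Randomised trials increasingly fit survival models in which the treatment
acts through more than one coefficient — a main effect plus a
treatment-by-covariate interaction — and in which the proportional-hazards
assumption may fail outright, with survival curves that cross. No single
hazard ratio summarises such a treatment. The restricted mean survival time
(RMST),

  μ(t\*) = ∫₀^t\* S(t) dt,

is the expected event-free time up to a truncation horizon t\*, and the
between-arm difference Δ(t\*) = μ₂(t\*) − μ₁(t\*) collapses the *combined*
treatment effect into one interpretable number that stays meaningful under
non-proportional hazards. The package is for trial statisticians who want to
test H₀: Δ(t\*) = 0 against H₁: Δ(t\*) > 0 with the one-sided statistic
Z = Δ̂(t\*) / s.e.(Δ̂(t\*)), and — more importantly — to *simulate* how that
test behaves when the analysis model is misspecified, before committing to
an analysis plan.

## What it provides

* **Model mathematics.** A piecewise-exponential proportional-hazards model
  with one knot t₁ (hazard λₐ·exp(βₐᵀx) before, λ·exp(βᵀx) after; t₁ = 0 is
  ordinary exponential PH): hazard, cumulative hazard, survival, exact
  closed-form conditional and covariate-averaged RMST, the true effect
  Δ(t\*), and root-finders for where crossing curves intersect and where
  the net area between them vanishes.
* **A trial simulator.** Bernoulli(0.5) binary covariates (treatment,
  inheritance pattern, sex, derived interaction), event times by
  cumulative-hazard inversion, exponential random censoring (rate
  0.001/week), uniform 0–20-week accrual and administrative censoring at
  study end (120 weeks).
* **Three estimators of Δ(t\*)** with standard errors and the one-sided
  Z-test: nonparametric Kaplan-Meier with Greenwood plug-in variance;
  correctly specified parametric maximum likelihood with delta-method
  variance; and misspecified parametric variants (sex omitted from the
  design, or the knot fitted at the wrong time).
* **A Monte-Carlo engine** for power, type I error, bias, Monte-Carlo
  standard errors and exclusion bookkeeping, with truncation-time,
  sex-coefficient and fitted-knot sweeps, paired evaluation across methods,
  and bitwise-reproducible seeding.
* **A command-line interface** (`inst/cli/rmstcomb`) with `simulate`,
  `estimate`, `study` and `presets` subcommands over packaged YAML
  scenario presets whose parameter values were informed by the public
  `cgd` gamma-interferon trial in chronic granulomatous disease.

## A worked example

Simulate one 130-subject trial from the crossing-curves working model (the
treatment coefficient switches from −1.117 to +0.750 at a 40-week knot) and
test the early treatment effect at t\* = 40 weeks:

```r
library(rmstcomb)
params <- cgd_nph_params()
trial  <- simulate_trial(params, 130, seed = 7)

z_test(rmst_nonparametric(trial, 40))
#>   t_star    delta       se        method defined        z reject alpha
#> 1     40 3.379348 2.051253 nonparametric    TRUE 1.647455  FALSE 0.025

fit <- fit_pwexp(trial, knot = 40)
z_test(rmst_parametric(fit, 40))
#>   t_star    delta       se     method defined        z reject alpha
#> 1     40 2.604473 1.693993 parametric    TRUE 1.537475  FALSE 0.025

true_delta(params, 40)
#>   t_star mu_treated mu_control    delta
#> 1     40   35.62105   30.77637 4.844674
```

This replication estimates a 3.4-week (nonparametric) or 2.6-week
(parametric) gain in event-free time over the first 40 weeks against a true
marginal effect of 4.84 weeks; neither Z exceeds the one-sided 2.5%
critical value 1.96, so this particular trial would not reject — single
trials of this size reject in roughly two-thirds of replications, which is
exactly the kind of statement the simulation engine quantifies:

```r
cfg <- read_scenario(system.file("extdata", "presets", "nph_cgd.yaml",
                                 package = "rmstcomb"))
operating_characteristics(cfg)   # power, bias, MCSE per method at t* = 40
```

The same works from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rmstcomb", package = "rmstcomb"))')
$CLI presets
$CLI simulate --config nph_cgd --out trial.csv --seed 7
$CLI estimate --data trial.csv --method parametric --knot 40 --t-star 40
$CLI study    --config nph_knot_sweep --out-dir results/ --reps 2000
```

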