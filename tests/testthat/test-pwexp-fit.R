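# Maximum-likelihood fitting of the (piecewise) exponential model.

test_that("log-likelihood reduces to the exponential closed form", {
  one <- as_subject_table(data.frame(time = 4, event = 1, treatment = 0,
                                     inherit = 0, sex = 0, entry_time = 0))
  # single subject, null model: log lambda - lambda * t, maximised at 1/t
  ll <- function(loglam) pwe_loglik(loglam, one, covariates = character(0))
  expect_equal(ll(log(0.25)), log(0.25) - 1)
  opt <- optimize(ll, c(-8, 2), maximum = TRUE)
  expect_equal(exp(opt$maximum), 1 / 4, tolerance = 1e-4)

  # with no events the likelihood is monotone decreasing in lambda
  cens <- as_subject_table(data.frame(time = c(3, 6), event = 0,
                                      treatment = 0, inherit = 0, sex = 0,
                                      entry_time = 0))
  lams <- seq(-6, 0, by = 0.5)
  lls <- vapply(lams, function(l) pwe_loglik(l, cens, character(0)),
                numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("analytic score vanishes at the optimum and matches finite diffs", {
  d <- sim_table(100)
  fit <- fit_pwexp(d)
  gr <- rmstcomb:::pwe_loglik_grad(fit$estimates, d, fit$covariates, 0)
  expect_lt(max(abs(gr)), 1e-5)
  # finite-difference check of the score at an arbitrary point
  par <- c(-4, -0.5, 0.2, -0.3, 0.1)
  num <- vapply(seq_along(par), function(j) {
    e <- numeric(5)
    e[j] <- 1e-6
    (pwe_loglik(par + e, d) - pwe_loglik(par - e, d)) / 2e-6
  }, numeric(1))
  expect_equal(rmstcomb:::pwe_loglik_grad(par, d, pwe_covariates, 0), num,
               tolerance = 1e-4)
})

test_that("exponential PH fit agrees with survreg", {
  skip_if_not_installed("survival")
  d <- sim_table(200, seed = 7)
  fit <- fit_pwexp(d)
  sr <- survival::survreg(
    survival::Surv(time, event) ~ treatment + inherit + sex +
      treatment_inherit, data = as.data.frame(d), dist = "exponential")
  # exponential AFT coefficients are the negated PH log-hazard coefficients
  expect_equal(unname(fit$estimates),
               unname(c(-coef(sr)[1], -coef(sr)[-1])), tolerance = 1e-5)
  expect_true(fit$converged)
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("generating coefficients are recovered at large n", {
  p <- ph_pars()
  d <- simulate_trial(p, 1e4, seed = 21)
  fit <- fit_pwexp(d)
  truth <- c(log(0.0158), unname(p$beta_b))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$estimates - truth) < 3.3 * se))

  np <- nph_pars()
  d2 <- simulate_trial(np, 2e4, seed = 22)
  fit2 <- fit_pwexp(d2, knot = 40)
  truth2 <- c(log(0.0158), unname(np$beta_a), log(0.0158), unname(np$beta_b))
  se2 <- sqrt(diag(fit2$vcov))
  expect_true(all(abs(fit2$estimates - truth2) < 3.3 * se2))
})

test_that("dropping a truly null covariate leaves the fit unchanged", {
  p <- pwe_params(0.0158, 0.0158, c(-1.117, 0.094, 0, 0.475),
                  c(-1.117, 0.094, 0, 0.475), 0)  # sex-free generator
  d <- simulate_trial(p, 5000, seed = 3)
  full <- fit_pwexp(d)
  nosex <- fit_pwexp(d, covariates = c("treatment", "inherit",
                                       "treatment_inherit"))
  shared <- c("log_lambda", "treatment", "inherit", "treatment_inherit")
  expect_equal(full$estimates[shared], nosex$estimates[shared],
               tolerance = 0.05)
})

test_that("inestimable configurations raise the classed condition", {
  # every treated subject censored: no event in half the combinations
  d <- as_subject_table(data.frame(
    time = c(5, 8, 10, 12), event = c(0, 0, 1, 1),
    treatment = c(1, 1, 0, 0), inherit = 0, sex = 0, entry_time = 0))
  expect_error(fit_pwexp(d, covariates = "treatment"),
               class = "pwe_inestimable")
  # an interval without any event makes its baseline inestimable
  d2 <- as_subject_table(data.frame(
    time = c(50, 60, 70, 80), event = 1,
    treatment = c(1, 1, 0, 0), inherit = 0, sex = 0, entry_time = 0))
  expect_error(fit_pwexp(d2, covariates = "treatment", knot = 40),
               class = "pwe_inestimable")
})

test_that("covariance is positive definite across a replication smoke run", {
  seeds <- rep_seeds(404, 120)
  ok <- 0
  for (s in seeds) {
    d <- simulate_trial(ph_pars(), 100, seed = s)
    fit <- tryCatch(fit_pwexp(d), pwe_inestimable = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    ok <- ok + 1
  }
  expect_gt(ok, 90)
})
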