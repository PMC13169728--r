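# Trial simulator: inversion correctness, censoring calibration behaviour,
# reproducibility and the CSV dialect.

test_that("event-time inversion satisfies the cumulative-hazard round trip", {
  np <- nph_pars()
  x <- covariate_profile(1, 1, 0)
  set.seed(5)
  u <- runif(200)
  tt <- draw_event_time(np, x, u)
  expect_equal(pwe_cumhaz(np, x, tt), -log(u), tolerance = 1e-10)

  # pure exponential branch
  p <- ph_pars()
  rate <- 0.0158 * exp(sum(p$beta_b * covariate_profile(1, 0, 1)))
  expect_equal(draw_event_time(p, covariate_profile(1, 0, 1), u),
               -log(u) / rate)
  # hand inversion: u = exp(-1.58) at the baseline rate gives exactly 100
  expect_equal(draw_event_time(p, covariate_profile(0, 0, 0), exp(-1.58)),
               100)
  expect_error(draw_event_time(p, covariate_profile(0, 0, 0), 0), "inside")
  expect_error(draw_event_time(p, covariate_profile(0, 0, 0), 1), "inside")
})

test_that("pre-knot event times are exponential with the pre-knot rate", {
  np <- nph_pars()
  x <- covariate_profile(0, 0, 0)
  set.seed(8)
  tt <- draw_event_time(np, x, runif(4e4))
  pre <- tt[tt < 40]
  # censored-at-40 exponential MLE of the rate from the truncated sample
  rate_hat <- length(pre) / (sum(pre) + 40 * sum(tt >= 40))
  expect_equal(rate_hat, 0.0158, tolerance = 0.03)
})

test_that("simulate_trial is reproducible and respects its contracts", {
  p <- ph_pars()
  a <- simulate_trial(p, 200, seed = 31)
  b <- simulate_trial(p, 200, seed = 31)
  expect_identical(a, b)
  expect_s3_class(a, "subject_table")
  expect_true(all(a$time > 0))
  expect_true(all(a$event %in% 0:1))
  expect_true(all(a$treatment_inherit == a$treatment * a$inherit))
  expect_true(all(a$entry_time >= 0 & a$entry_time <= 20))
  expect_true(all(a$time <= 120 - a$entry_time + 1e-12))

  # no censoring mechanism at all: every subject has an event
  none <- censoring_config(random_rate = 0, accrual_window = 1,
                           study_end = 1e7)
  d <- simulate_trial(p, 300, censoring = none, seed = 4)
  expect_true(all(d$event == 1))
  expect_error(simulate_trial(p, 0), ">= 1")
})

test_that("censored fractions move monotonically with the mechanisms", {
  p <- ph_pars()
  frac <- function(rate, end) {
    d <- simulate_trial(p, 4000,
                        censoring_config(random_rate = rate, study_end = end),
                        seed = 55, latent = TRUE)
    c(random = mean(d$censor_time < pmin(d$event_time, d$admin_time)),
      overall = mean(d$event == 0))
  }
  f1 <- frac(0.0005, 120)
  f2 <- frac(0.002, 120)
  f3 <- frac(0.008, 120)
  expect_true(f1["random"] < f2["random"] && f2["random"] < f3["random"])
  g1 <- frac(0.001, 60)
  g2 <- frac(0.001, 120)
  g3 <- frac(0.001, 240)
  expect_true(g1["overall"] > g2["overall"] && g2["overall"] > g3["overall"])
})

test_that("large-sample KM of an uncensored cohort matches marginal survival", {
  np <- nph_pars()
  none <- censoring_config(random_rate = 0, accrual_window = 1,
                           study_end = 1e7)
  d <- simulate_trial(np, 1e5, censoring = none, seed = 77)
  for (arm in 0:1) {
    tt <- sort(d$time[d$treatment == arm])
    # all events: empirical survival is 1 - ecdf
    grid <- seq(1, 120, by = 1)
    emp <- 1 - stats::ecdf(tt)(grid)
    expect_lt(max(abs(emp - marginal_survival(np, arm, grid))), 0.02)
  }
})

test_that("null_params removes every treatment effect and is idempotent", {
  for (p in list(ph_pars(), nph_pars())) {
    p0 <- null_params(p)
    expect_equal(max(abs(true_delta(p0, c(20, 60, 100))$delta)), 0)
    expect_identical(null_params(p0), p0)
    expect_equal(p0$beta_a[c("inherit", "sex")], p$beta_a[c("inherit", "sex")])
  }
  expect_true(is.na(crossing_time(null_params(nph_pars()), 1, 120)))
})

test_that("subject tables round-trip through the canonical CSV dialect", {
  d <- simulate_trial(ph_pars(), 40, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_subject_table(d, f)
  header <- readLines(f, n = 1)
  expect_identical(header, "time,event,treatment,inherit,sex,entry_time")
  d2 <- read_subject_table(f)
  expect_equal(d2$time, d$time, tolerance = 1e-6)
  expect_identical(d2$event, d$event)
  expect_identical(d2$treatment_inherit, d$treatment_inherit)
  expect_error(as_subject_table(data.frame(time = 1)), "missing columns")
  expect_error(as_subject_table(data.frame(time = 1, event = 2, treatment = 0,
                                           inherit = 0, sex = 0)), "binary")
})
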