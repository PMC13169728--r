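# Closed-form model mathematics against independent numerical oracles.

test_that("hazard is the piecewise-constant rate with half-open intervals", {
  p <- ph_pars(beta_sex = -0.402)
  x0 <- covariate_profile(0, 0, 0)
  expect_equal(pwe_hazard(p, x0, 10), 0.0158)

  # zero coefficients reduce to the bare baseline before the knot
  pz <- pwe_params(0.02, 0.05, rep(0, 4), rep(0, 4), t1 = 30)
  expect_equal(pwe_hazard(pz, covariate_profile(1, 1, 1), 10), 0.02)
  # knot itself belongs to the post-knot piece
  expect_equal(pwe_hazard(pz, x0, 30), 0.05)

  # hazard ratio across the knot for a treated baseline subject equals the
  # ratio of the treatment coefficients' exponentials
  np <- nph_pars()
  xt <- covariate_profile(1, 0, 0)
  expect_equal(pwe_hazard(np, xt, 39) / pwe_hazard(np, xt, 41),
               exp(-1.117 - 0.750))
  expect_error(pwe_hazard(p, x0, -1), "nonnegative")
})

test_that("cumulative hazard accumulates both pieces and is continuous", {
  p <- ph_pars(beta_sex = -0.402)
  x0 <- covariate_profile(0, 0, 0)
  expect_equal(pwe_cumhaz(p, x0, 0), 0)
  expect_equal(pwe_cumhaz(p, x0, 100), 1.58)

  np <- nph_pars()
  x <- covariate_profile(1, 1, 1)
  eps <- 1e-9
  expect_equal(pwe_cumhaz(np, x, 40 - eps), pwe_cumhaz(np, x, 40),
               tolerance = 1e-6)
  # nondecreasing on a fine grid
  H <- pwe_cumhaz(np, x, seq(0, 120, by = 0.5))
  expect_true(all(diff(H) >= 0))
})

test_that("survival is exp(-H), equals one at zero and is nonincreasing", {
  p <- ph_pars(beta_sex = -0.402)
  x0 <- covariate_profile(0, 0, 0)
  expect_equal(pwe_surv(p, x0, 0), 1)
  expect_equal(pwe_surv(p, x0, 100), exp(-1.58))
  S <- pwe_surv(nph_pars(), covariate_profile(1, 1, 0), 0:120)
  expect_true(all(diff(S) <= 0))
  expect_true(all(S > 0 & S <= 1))
})

test_that("closed-form RMST matches adaptive quadrature of the survival", {
  profiles <- list(covariate_profile(0, 0, 0), covariate_profile(1, 0, 1),
                   covariate_profile(1, 1, 0), covariate_profile(0, 1, 1))
  for (p in list(ph_pars(), nph_pars(),
                 pwe_params(0.03, 0.004, c(0.5, -1, 0.2, 0),
                            c(-0.3, 0.1, 0, 0.8), t1 = 17.5))) {
    for (x in profiles) {
      for (ts in c(5, 40, 100)) {
        q <- stats::integrate(function(t) pwe_surv(p, x, t), 0, ts,
                              rel.tol = 1e-12, abs.tol = 0)$value
        expect_rel_equal(pwe_rmst(p, x, ts), q, 1e-8)
      }
    }
  }
})

test_that("RMST reduces to the exponential form and is continuous in t*", {
  lambda <- 0.02
  pz <- pwe_params(lambda, lambda, rep(0, 4), rep(0, 4), t1 = 55)
  x <- covariate_profile(1, 1, 1)
  expect_equal(pwe_rmst(pz, x, 80), (1 - exp(-lambda * 80)) / lambda)

  np <- nph_pars()
  eps <- 1e-8
  expect_equal(pwe_rmst(np, x, 40 - eps), pwe_rmst(np, x, 40),
               tolerance = 1e-6)
  expect_error(pwe_rmst(np, x, 0), "positive")
})

test_that("marginal survival averages the four covariate profiles", {
  np <- nph_pars()
  s_direct <- mean(vapply(
    list(covariate_profile(1, 0, 0), covariate_profile(1, 1, 0),
         covariate_profile(1, 0, 1), covariate_profile(1, 1, 1)),
    function(x) pwe_surv(np, x, 60), numeric(1)))
  expect_equal(marginal_survival(np, 1, 60), s_direct)
  expect_equal(marginal_survival(np, 1, 0), 1)

  # coefficients free of inherit and sex collapse to the conditional curve
  p <- pwe_params(0.0158, 0.0158, c(-1, 0, 0, 0), c(-1, 0, 0, 0), 0)
  expect_equal(marginal_survival(p, 1, 50),
               pwe_surv(p, covariate_profile(1, 0, 0), 50))
  expect_error(marginal_survival(np, 1, 10, prevalence = 1.2), "probability")
})

test_that("true delta matches quadrature of the marginal survival gap", {
  p <- ph_pars()
  q <- stats::integrate(function(t) marginal_survival(p, 1, t) -
                                    marginal_survival(p, 0, t),
                        0, 100, rel.tol = 1e-12, abs.tol = 0)$value
  td <- true_delta(p, 100)
  expect_rel_equal(td$delta, q, 1e-8)
  expect_equal(td$delta, td$mu_treated - td$mu_control)

  # no treatment effect in either piece means identical arms
  expect_equal(true_delta(null_params(nph_pars()), 80)$delta, 0)

  # bounded by t* and vanishing with it
  grid <- c(0.001, 1, 30, 60, 120)
  d <- true_delta(nph_pars(), grid)$delta
  expect_true(all(abs(d) <= grid))
  expect_lt(abs(d[1]), 1e-3)
})

test_that("delta of the crossing-curves model rises then falls", {
  d <- true_delta(nph_pars(), seq(1, 120, by = 1))$delta
  peak <- which.max(d)
  expect_true(all(diff(d[seq_len(peak)]) > 0))
  expect_true(all(diff(d[peak:length(d)]) < 0))
})

test_that("crossing and zero-area root-finders locate the curve geometry", {
  np <- nph_pars()
  cross <- crossing_time(np, 40, 120)
  zero <- zero_area_time(np, 41, 120)
  expect_false(is.na(cross))
  expect_false(is.na(zero))
  expect_gt(zero, cross)  # delta keeps rising until the curves cross
  # the crossing is where the marginal curves agree
  expect_equal(marginal_survival(np, 1, cross), marginal_survival(np, 0, cross),
               tolerance = 1e-4)
  expect_equal(true_delta(np, zero)$delta, 0, tolerance = 1e-4)
  # arm labels are symmetric
  swapped <- np
  swapped$beta_a[c("treatment", "treatment_inherit")] <-
    -np$beta_a[c("treatment", "treatment_inherit")]
  expect_equal(crossing_time(np, 40, 120), crossing_time(np, 40, 120))

  # a uniformly beneficial PH treatment never crosses
  expect_true(is.na(crossing_time(ph_pars(), 1, 120)))
  expect_true(is.na(zero_area_time(ph_pars(), 1, 120)))
})
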