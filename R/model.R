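# Closed-form mathematics of the piecewise-exponential model: hazard,
# cumulative hazard, survival, conditional and marginal RMST, true treatment
# effect, and the root-finding utilities for curve geometry.

# Subject-specific rates before/after the knot. x may be a length-4 vector or
# an n x 4 matrix; returns list(ra, rb) of length n.
pwe_rates <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != 4L) stop("covariate profile must have 4 columns")
  list(ra = params$lambda_a * exp(drop(x %*% params$beta_a)),
       rb = params$lambda_b * exp(drop(x %*% params$beta_b)))
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("time 't' must be finite and nonnegative")
  t
}

#' Hazard, cumulative hazard and survival of the piecewise model
#'
#' `pwe_hazard()` evaluates the piecewise-constant hazard
#' `lambda_a exp(beta_a' x)` for `t < t1` and `lambda_b exp(beta_b' x)`
#' otherwise (the knot itself belongs to the post-knot piece).
#' `pwe_cumhaz()` integrates it from 0, and `pwe_surv()` is
#' `exp(-cumhaz)`. All three are vectorised over `t`.
#'
#' @param params A [pwe_params()] object.
#' @param x Covariate profile from [covariate_profile()] (length-4 vector).
#' @param t Time(s) in weeks, `>= 0`.
#' @return Numeric vector the length of `t`.
#' @export
pwe_hazard <- function(params, x, t) {
  check_time(t)
  r <- pwe_rates(params, x)
  ifelse(t < params$t1, r$ra, r$rb)
}

#' @rdname pwe_hazard
#' @export
pwe_cumhaz <- function(params, x, t) {
  check_time(t)
  r <- pwe_rates(params, x)
  t1 <- params$t1
  ifelse(t < t1, r$ra * t, r$ra * t1 + r$rb * (t - t1))
}

#' @rdname pwe_hazard
#' @export
pwe_surv <- function(params, x, t) {
  exp(-pwe_cumhaz(params, x, t))
}

# Conditional RMST for given pre/post rates; vectorised over t_star.
# mu = (1 - exp(-ra*min(t*,t1)))/ra + 1{t*>t1} exp(-ra*t1)(1-exp(-rb*(t*-t1)))/rb
# which is the exact integral of exp(-H(t)) on [0, t*] and reduces to the
# single-exponential form (1 - exp(-rb t*))/rb when t1 = 0.
rmst_from_rates <- function(ra, rb, t1, t_star) {
  pre <- (1 - exp(-ra * pmin(t_star, t1))) / ra
  post <- ifelse(t_star > t1,
                 exp(-ra * t1) * (1 - exp(-rb * pmax(t_star - t1, 0))) / rb,
                 0)
  pre + post
}

#' Conditional restricted mean survival time
#'
#' Closed-form RMST `mu(t*) = integral of S(t | x) over [0, t*]` for a
#' subject with covariate profile `x` under the piecewise-exponential model.
#' Vectorised over `t_star`.
#'
#' @inheritParams pwe_hazard
#' @param t_star Truncation time(s) in weeks, `> 0`.
#' @return Numeric vector of restricted means, each in `(0, t_star]`.
#' @export
pwe_rmst <- function(params, x, t_star) {
  if (!is.numeric(t_star) || any(!is.finite(t_star)) || any(t_star <= 0))
    stop("'t_star' must be finite and strictly positive")
  r <- pwe_rates(params, x)
  rmst_from_rates(r$ra, r$rb, params$t1, t_star)
}

#' Marginal survival of one treatment arm
#'
#' Survival probability averaged over the distribution of the non-treatment
#' covariates: the four `(inherit, sex)` combinations are weighted by
#' independent Bernoulli(`prevalence`) probabilities, with treatment fixed at
#' `arm` and the interaction set to `arm * inherit`. This is the survival
#' curve a Kaplan-Meier estimate of the arm converges to.
#'
#' @inheritParams pwe_hazard
#' @param arm Treatment arm, 0 (control) or 1 (treated).
#' @param prevalence Bernoulli prevalence of `inherit` and `sex`.
#' @return Numeric vector the length of `t`.
#' @export
marginal_survival <- function(params, arm, t, prevalence = 0.5) {
  stopifnot(arm %in% c(0, 1))
  check_time(t)
  g <- profile_grid(arm, prevalence)
  s <- vapply(seq_len(nrow(g$X)),
              function(i) pwe_surv(params, g$X[i, ], t),
              numeric(length(t)))
  drop(matrix(s, nrow = length(t)) %*% g$w)
}

#' True RMST treatment effect of a generating model
#'
#' The estimand targeted by every estimator in the package: the difference in
#' covariate-averaged RMST between the treated and control arms,
#' `Delta(t*) = mu_treated(t*) - mu_control(t*)`, where each arm's RMST is
#' the equal-prevalence average of the conditional closed form over the four
#' `(inherit, sex)` combinations. By linearity of the integral this equals
#' the area between the marginal survival curves up to `t*`.
#'
#' @inheritParams marginal_survival
#' @param t_star Truncation time(s) in weeks, `> 0`.
#' @return A data frame with columns `t_star`, `mu_treated`, `mu_control`,
#'   `delta` (one row per truncation time).
#' @export
true_delta <- function(params, t_star, prevalence = 0.5) {
  mu_arm <- function(arm) {
    g <- profile_grid(arm, prevalence)
    m <- vapply(seq_len(nrow(g$X)),
                function(i) pwe_rmst(params, g$X[i, ], t_star),
                numeric(length(t_star)))
    drop(matrix(m, nrow = length(t_star)) %*% g$w)
  }
  mu1 <- mu_arm(1)
  mu0 <- mu_arm(0)
  data.frame(t_star = t_star, mu_treated = mu1, mu_control = mu0,
             delta = mu1 - mu0)
}

# Bracketed root of f on (lower, upper); NA_real_ when f keeps one sign.
bracket_root <- function(f, lower, upper, tol) {
  fl <- f(lower)
  fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu)) stop("objective not finite on bracket")
  if (fl == 0 && fu == 0) return(NA_real_)  # identical curves: no crossing
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  if (sign(fl) == sign(fu)) return(NA_real_)
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Geometry of the marginal survival curves
#'
#' `crossing_time()` locates the time at which the marginal survival curves
#' of the two arms intersect; `zero_area_time()` locates the truncation time
#' at which the true RMST difference `Delta(t*)` returns to zero (the net
#' area between the curves vanishes). Both use bracketed root-finding and
#' return `NA` when the respective function does not change sign on the
#' bracket (e.g. under proportional hazards with a uniformly beneficial
#' treatment).
#'
#' @inheritParams marginal_survival
#' @param lower,upper Bracket endpoints in weeks.
#' @param tol Root location tolerance in weeks.
#' @return Time in weeks, or `NA_real_` if there is no sign change.
#' @export
crossing_time <- function(params, lower = 0, upper = 120, prevalence = 0.5,
                          tol = 1e-3) {
  f <- function(t) marginal_survival(params, 1, t, prevalence) -
                   marginal_survival(params, 0, t, prevalence)
  bracket_root(f, lower, upper, tol)
}

#' @rdname crossing_time
#' @export
zero_area_time <- function(params, lower = 1e-6, upper = 120,
                           prevalence = 0.5, tol = 1e-3) {
  f <- function(t) true_delta(params, t, prevalence)$delta
  bracket_root(f, lower, upper, tol)
}
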