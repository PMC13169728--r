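# Nonparametric RMST: product-limit survival estimate and the restricted-mean
# functional with Greenwood plug-in variance.

#' Kaplan-Meier fit of one treatment arm
#'
#' Product-limit estimate computed at the distinct event times of the arm;
#' censoring acts by shrinking the risk set between event times.
#'
#' @param table A `subject_table` (see [as_subject_table()]).
#' @param arm Treatment arm, 0 or 1.
#' @return An object of class `km_curve` with components `event_times`,
#'   `survival`, `n_at_risk`, `n_events` (all aligned vectors), `n` (arm
#'   size) and `max_time` (largest observed time, the limit of definedness
#'   for restricted means).
#' @export
km_fit <- function(table, arm) {
  stopifnot(inherits(table, "subject_table"), arm %in% c(0, 1))
  sub <- table[table$treatment == arm, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no subjects in arm ", arm)
  time <- sub$time
  event <- sub$event
  tau <- sort(unique(time[event == 1]))
  if (length(tau)) {
    d <- vapply(tau, function(tt) sum(time == tt & event == 1), numeric(1))
    n_risk <- vapply(tau, function(tt) sum(time >= tt), numeric(1))
    surv <- cumprod(1 - d / n_risk)
  } else {
    d <- n_risk <- surv <- numeric(0)
  }
  structure(list(event_times = tau, survival = surv, n_at_risk = n_risk,
                 n_events = d, n = nrow(sub), max_time = max(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", length(x$event_times),
      "distinct event times, max observed time",
      format(round(x$max_time, 2)), "\n")
  invisible(x)
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Area under the product-limit step function up to each `t_star` (rectangle
#' sum over event times plus the terminal partial rectangle), with the
#' Greenwood plug-in variance for restricted means:
#' `Var = sum over event times tau_i <= t* of A_i^2 d_i / (n_i (n_i - d_i))`
#' where `A_i` is the area under the curve from `tau_i` to `t*`. Terms with
#' `n_i == d_i` (absorption: the curve hits zero) contribute nothing since
#' `A_i = 0` there, and are dropped.
#'
#' The restricted mean is only defined while at least one subject remains at
#' risk, i.e. for `t_star <= max_time`; later truncation times are flagged
#' `defined = FALSE` with `NA` estimates.
#'
#' @param curve A [km_fit()] result.
#' @param t_star Truncation time(s) in weeks, `> 0`; vectorised.
#' @return A data frame with columns `t_star`, `rmst`, `var`, `defined`.
#' @export
km_rmst <- function(curve, t_star) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t_star <= 0)) stop("'t_star' must be strictly positive")
  tau <- curve$event_times
  s <- curve$survival
  d <- curve$n_events
  n <- curve$n_at_risk
  # area under the step function from 0 to each tau_i (left limits):
  # S = 1 on [0, tau_1), s[i] on [tau_i, tau_{i+1})
  k <- length(tau)
  s_left <- c(1, s[-k])                       # value on the gap ending at tau_i
  gaps <- diff(c(0, tau))
  area_at_tau <- cumsum(s_left * gaps)        # integral 0..tau_i
  res <- lapply(t_star, function(ts) {
    if (ts > curve$max_time)
      return(c(rmst = NA_real_, var = NA_real_, defined = 0))
    idx <- which(tau <= ts)
    if (!length(idx))
      return(c(rmst = ts, var = 0, defined = 1))
    m <- max(idx)
    total <- area_at_tau[m] + s[m] * (ts - tau[m])
    A <- total - area_at_tau[idx]             # integral tau_i .. ts
    keep <- n[idx] > d[idx]
    v <- sum(A[keep]^2 * d[idx][keep] / (n[idx][keep] *
                                         (n[idx][keep] - d[idx][keep])))
    c(rmst = total, var = v, defined = 1)
  })
  res <- do.call(rbind, res)
  data.frame(t_star = t_star, rmst = res[, "rmst"], var = res[, "var"],
             defined = res[, "defined"] == 1)
}

#' Nonparametric RMST difference between arms
#'
#' Fits a Kaplan-Meier curve per arm, computes each arm's restricted mean and
#' Greenwood variance via [km_rmst()], and combines them by independence:
#' `delta = mu_treated - mu_control`, `se = sqrt(var_treated + var_control)`.
#' Truncation times beyond either arm's last observed time are undefined
#' (`defined = FALSE`), the condition that drives study-level exclusions.
#'
#' @param table A `subject_table` containing both arms.
#' @param t_star Truncation time(s) in weeks; vectorised.
#' @return An `rmst_estimate` data frame with columns `t_star`, `delta`,
#'   `se`, `method` (`"nonparametric"`) and `defined`.
#' @export
rmst_nonparametric <- function(table, t_star) {
  fit1 <- km_fit(table, 1)
  fit0 <- km_fit(table, 0)
  a1 <- km_rmst(fit1, t_star)
  a0 <- km_rmst(fit0, t_star)
  out <- data.frame(t_star = t_star,
                    delta = a1$rmst - a0$rmst,
                    se = sqrt(a1$var + a0$var),
                    method = "nonparametric",
                    defined = a1$defined & a0$defined)
  class(out) <- c("rmst_estimate", "data.frame")
  out
}

#' One-sided Z-test for an RMST difference
#'
#' Computes `z = delta / se` and rejects the null of no combined treatment
#' effect when `z` exceeds the upper-`alpha` standard-normal quantile
#' (1.959964 at the default one-sided 2.5% level).
#'
#' @param est An `rmst_estimate` data frame (from [rmst_nonparametric()] or
#'   [rmst_parametric()]); rows with `defined = FALSE` get `NA` results.
#' @param alpha One-sided significance level.
#' @return The input with columns `z`, `reject` and `alpha` appended.
#' @export
z_test <- function(est, alpha = 0.025) {
  stopifnot(inherits(est, "rmst_estimate"), alpha > 0, alpha < 1)
  ok <- est$defined
  if (any(est$se[ok] <= 0)) stop("standard errors must be positive")
  est$z <- ifelse(ok, est$delta / est$se, NA_real_)
  est$reject <- est$z > stats::qnorm(1 - alpha)
  est$alpha <- alpha
  class(est) <- c("rmst_test", class(est))
  est
}
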