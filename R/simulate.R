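# Trial simulator: Bernoulli covariates, piecewise-exponential event times by
# cumulative-hazard inversion, exponential random censoring, uniform accrual
# and administrative censoring at study end.

#' Censoring and accrual configuration
#'
#' @param random_rate Rate (per week) of the exponential random-censoring
#'   mechanism; `0` disables it.
#' @param accrual_window Length of the uniform accrual window in weeks;
#'   subjects enter the study at `Uniform(0, accrual_window)` calendar times.
#' @param study_end Calendar time (weeks) at which the study closes; every
#'   subject still at risk is administratively censored at
#'   `study_end - entry_time` on their own follow-up clock.
#' @return An object of class `censoring_config`.
#' @export
censoring_config <- function(random_rate = 0.001, accrual_window = 20,
                             study_end = 120) {
  stopifnot(is.numeric(random_rate), length(random_rate) == 1L,
            is.numeric(accrual_window), length(accrual_window) == 1L,
            is.numeric(study_end), length(study_end) == 1L)
  if (random_rate < 0) stop("'random_rate' must be nonnegative")
  if (accrual_window < 0) stop("'accrual_window' must be nonnegative")
  if (study_end <= accrual_window)
    stop("'study_end' must exceed 'accrual_window'")
  structure(list(random_rate = random_rate, accrual_window = accrual_window,
                 study_end = study_end),
            class = "censoring_config")
}

#' Draw an event time by inverting the cumulative hazard
#'
#' Transforms a uniform draw `u` into an event time under the
#' piecewise-exponential model: with `E = -log(u) ~ Exp(1)`, the event time
#' is `T = H^{-1}(E | x)`. The inverse has two branches: if `E` is below the
#' hazard accumulated up to the knot, `T = E / (lambda_a exp(beta_a' x))`;
#' otherwise the remainder accrues at the post-knot rate. With `t1 = 0` this
#' is the familiar exponential inversion `T = -log(u) / rate`. The
#' round-trip identity `pwe_cumhaz(params, x, T) == -log(u)` holds exactly.
#'
#' @inheritParams pwe_hazard
#' @param u Uniform(0, 1) draw(s); vectorised.
#' @return Event time(s) in weeks.
#' @export
draw_event_time <- function(params, x, u) {
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1)")
  r <- pwe_rates(params, x)
  e <- -log(u)
  invert_cumhaz(e, r$ra, r$rb, params$t1)
}

# Vectorised inverse cumulative hazard; e, ra, rb conformable vectors.
invert_cumhaz <- function(e, ra, rb, t1) {
  h1 <- ra * t1
  ifelse(e < h1, e / ra, t1 + (e - h1) / rb)
}

#' Simulate one trial replication
#'
#' Generates `n` subjects with the structure of a two-arm randomised trial:
#' treatment, inheritance pattern and sex are independent
#' Bernoulli(`prevalence`) indicators (the interaction is derived); event
#' times come from [draw_event_time()] on each subject's own follow-up
#' clock; entry times are Uniform(0, accrual window); random censoring times
#' are exponential with the configured rate; and administrative censoring
#' occurs at `study_end - entry_time`. The observed time is the minimum of
#' the three and `event = 1` exactly when the event time attains it (ties,
#' which have probability zero, resolve in favour of the event).
#'
#' For a fixed `seed` the output is reproducible; draws are consumed in a
#' fixed stream order (treatment, inherit, sex vectors; event uniforms;
#' random censoring times; entry times) so that the covariate pattern is
#' unchanged when only the censoring configuration varies.
#'
#' @param params A [pwe_params()] generating model.
#' @param n Number of subjects, `>= 1`.
#' @param censoring A [censoring_config()].
#' @param prevalence Bernoulli prevalence of each binary covariate.
#' @param seed Optional integer seed set before drawing.
#' @param latent If `TRUE`, keep the latent `event_time`, `censor_time` and
#'   `admin_time` columns alongside the observed data (useful for censoring
#'   diagnostics).
#' @return A `subject_table`: a data frame with columns `time`, `event`,
#'   `treatment`, `inherit`, `sex`, `entry_time` and the derived
#'   `treatment_inherit`.
#' @export
simulate_trial <- function(params, n, censoring = censoring_config(),
                           prevalence = 0.5, seed = NULL, latent = FALSE) {
  stopifnot(inherits(params, "pwe_params"),
            inherits(censoring, "censoring_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  if (prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be a probability")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  treatment <- stats::rbinom(n, 1L, prevalence)
  inherit <- stats::rbinom(n, 1L, prevalence)
  sex <- stats::rbinom(n, 1L, prevalence)
  X <- cbind(treatment = treatment, inherit = inherit, sex = sex,
             treatment_inherit = treatment * inherit)
  u <- stats::runif(n)
  r <- pwe_rates(params, X)
  event_time <- invert_cumhaz(-log(u), r$ra, r$rb, params$t1)
  censor_time <- if (censoring$random_rate > 0)
    stats::rexp(n, censoring$random_rate) else rep(Inf, n)
  entry_time <- stats::runif(n, 0, censoring$accrual_window)
  admin_time <- censoring$study_end - entry_time

  time <- pmin(event_time, censor_time, admin_time)
  event <- as.integer(event_time <= pmin(censor_time, admin_time))
  out <- data.frame(time = time, event = event, treatment = treatment,
                    inherit = inherit, sex = sex, entry_time = entry_time,
                    treatment_inherit = treatment * inherit)
  if (latent) {
    out$event_time <- event_time
    out$censor_time <- censor_time
    out$admin_time <- admin_time
  }
  as_subject_table(out)
}

#' Subject-level trial data
#'
#' `as_subject_table()` validates a data frame of subject-level survival data
#' (columns `time`, `event`, `treatment`, `inherit`, `sex` and optionally
#' `entry_time`), derives the `treatment_inherit` interaction column, and
#' stamps the `subject_table` class. `read_subject_table()` and
#' `write_subject_table()` exchange the canonical CSV dialect with header
#' `time,event,treatment,inherit,sex,entry_time` (times in weeks, 6-decimal
#' fixed format; the interaction column is derived, not stored).
#'
#' @param x A data frame.
#' @return A `subject_table` data frame.
#' @export
as_subject_table <- function(x) {
  x <- as.data.frame(x)
  required <- c("time", "event", "treatment", "inherit", "sex")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) stop("subject table must contain at least one subject")
  if (any(x$time <= 0)) stop("observed times must be strictly positive")
  for (col in c("event", "treatment", "inherit", "sex"))
    if (!all(x[[col]] %in% c(0, 1)))
      stop("column '", col, "' must be binary 0/1")
  x$treatment_inherit <- x$treatment * x$inherit
  if (is.null(x$entry_time)) x$entry_time <- 0
  class(x) <- c("subject_table", "data.frame")
  x
}

#' @rdname as_subject_table
#' @param path File path of a CSV in the canonical dialect.
#' @export
read_subject_table <- function(path) {
  as_subject_table(utils::read.csv(path))
}

#' @rdname as_subject_table
#' @param table A `subject_table`.
#' @export
write_subject_table <- function(table, path) {
  stopifnot(inherits(table, "subject_table"))
  out <- table[, c("time", "event", "treatment", "inherit", "sex",
                   "entry_time")]
  out$time <- sprintf("%.6f", out$time)
  out$entry_time <- sprintf("%.6f", out$entry_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
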