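# Monte-Carlo engine: scenario configuration, replication runner, operating
# characteristics (power / type I error, bias, MCSE) and the t*, beta3 and
# knot sweeps.

#' Estimator variants evaluated in a simulation scenario
#'
#' `method_nonparametric()` declares the Kaplan-Meier RMST difference;
#' `method_parametric()` declares a maximum-likelihood piecewise-exponential
#' variant with a given covariate subset and fitted knot (the fitted knot
#' need not equal the generator's knot, which is how knot misspecification
#' is expressed; omitting `sex` from `covariates` is how covariate
#' misspecification is expressed).
#'
#' @param name Label used in result tables.
#' @param covariates Covariate subset included in the fitted model.
#' @param knot Fitted knot time in weeks (`0` = exponential PH fit).
#' @return A method descriptor (list) consumed by [scenario_config()].
#' @export
method_nonparametric <- function(name = "nonparametric") {
  list(name = name, type = "nonparametric")
}

#' @rdname method_nonparametric
#' @export
method_parametric <- function(name, covariates = pwe_covariates, knot = 0) {
  bad <- setdiff(covariates, pwe_covariates)
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  if (knot < 0) stop("'knot' must be nonnegative")
  list(name = name, type = "parametric", covariates = covariates, knot = knot)
}

#' Simulation scenario configuration
#'
#' Everything needed to regenerate one simulation scenario: the generating
#' model, trial size, censoring/accrual settings, truncation-time grid, the
#' estimator variants to evaluate, the replication count and the master
#' seed. Under `hypothesis = "null"` the data are generated from
#' [null_params()] of the generator (identical arms, covariate structure
#' preserved) and the true RMST difference is zero, so rejection rates are
#' type I error; under `"alternative"` they are power.
#'
#' @param generator A [pwe_params()] generating model.
#' @param n_subjects Subjects per simulated trial.
#' @param censoring A [censoring_config()].
#' @param t_star Truncation-time grid (weeks), all in `(0, study_end]`.
#' @param methods List of method descriptors ([method_nonparametric()],
#'   [method_parametric()]); names must be unique.
#' @param n_reps Number of Monte-Carlo replications.
#' @param seed Master seed; replication seeds are derived from it.
#' @param hypothesis `"alternative"` or `"null"`.
#' @param prevalence Bernoulli covariate prevalence.
#' @param alpha One-sided test level.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(generator, n_subjects,
                            censoring = censoring_config(),
                            t_star, methods, n_reps, seed,
                            hypothesis = c("alternative", "null"),
                            prevalence = 0.5, alpha = 0.025) {
  stopifnot(inherits(generator, "pwe_params"),
            inherits(censoring, "censoring_config"),
            n_subjects >= 1, n_reps >= 1, length(methods) >= 1)
  hypothesis <- match.arg(hypothesis)
  if (any(t_star <= 0) || any(t_star > censoring$study_end))
    stop("'t_star' values must lie in (0, study_end]")
  nms <- vapply(methods, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("method names must be unique")
  names(methods) <- nms
  structure(list(generator = generator, n_subjects = as.integer(n_subjects),
                 censoring = censoring, t_star = as.numeric(t_star),
                 methods = methods, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), hypothesis = hypothesis,
                 prevalence = prevalence, alpha = alpha),
            class = "scenario_config")
}

#' Replication seeds derived from a master seed
#'
#' Deterministic stream of per-replication seeds: the master seed seeds a
#' draw of `n` distinct integers, so any single replication can be
#' regenerated independently of the others.
#'
#' @param master_seed Integer master seed.
#' @param n Number of replications.
#' @return Integer vector of length `n`.
#' @export
rep_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

effective_generator <- function(config) {
  if (config$hypothesis == "null") null_params(config$generator)
  else config$generator
}

# Evaluate every configured method on one simulated table at every t*.
# Returns list per method: data.frame(t_star, delta, se, defined, reason).
evaluate_table <- function(table, config) {
  lapply(config$methods, function(m) {
    if (m$type == "nonparametric") {
      est <- tryCatch(rmst_nonparametric(table, config$t_star),
                      error = function(e) NULL)  # e.g. an empty arm
      if (is.null(est))
        return(data.frame(t_star = config$t_star, delta = NA_real_,
                          se = NA_real_, method = m$name, defined = FALSE,
                          reason = "empty_arm"))
      est$reason <- ifelse(est$defined, "", "undefined_at_t_star")
      est$method <- m$name
      est
    } else {
      fit <- tryCatch(fit_pwexp(table, m$covariates, m$knot),
                      pwe_inestimable = function(e) e)
      if (inherits(fit, "condition") || !fit$converged) {
        reason <- if (inherits(fit, "condition")) "inestimable"
                  else "nonconvergence"
        data.frame(t_star = config$t_star, delta = NA_real_, se = NA_real_,
                   method = m$name, defined = FALSE, reason = reason)
      } else {
        est <- rmst_parametric(fit, config$t_star, config$prevalence,
                               method = m$name)
        est$reason <- ""
        est
      }
    }
  })
}

#' Run a single replication of a scenario
#'
#' Simulates one trial (seed derived from the master seed and the
#' replication index) and evaluates every configured estimator at every
#' truncation time on the same table. Statistical degeneracies (no subject
#' at risk at `t*` for the nonparametric estimator; a covariate combination
#' without events for the parametric ones) are reported as exclusion flags,
#' not errors.
#'
#' @param config A [scenario_config()].
#' @param rep_index Replication number in `1..n_reps`.
#' @return A long data frame with one row per (method, t_star): columns
#'   `rep`, `method`, `t_star`, `delta`, `se`, `z`, `reject`, `defined`,
#'   `reason`.
#' @export
run_replication <- function(config, rep_index) {
  stopifnot(inherits(config, "scenario_config"),
            rep_index >= 1, rep_index <= config$n_reps)
  seed <- rep_seeds(config$seed, config$n_reps)[rep_index]
  table <- simulate_trial(effective_generator(config), config$n_subjects,
                          config$censoring, config$prevalence, seed = seed)
  res <- evaluate_table(table, config)
  out <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    r$method <- nm
    r
  }))
  # se = 0 can only arise for the nonparametric estimator before any event
  # (both restricted means equal t*, delta = 0): the test does not reject.
  out$z <- ifelse(out$defined, ifelse(out$se > 0, out$delta / out$se, 0),
                  NA_real_)
  out$reject <- out$z > stats::qnorm(1 - config$alpha)
  cbind(rep = rep_index, out)
}

#' Operating characteristics of a scenario
#'
#' Runs all replications and aggregates, per method and truncation time:
#' the rejection rate of the one-sided Z-test (power under the alternative,
#' type I error under the null) with its binomial Monte-Carlo standard
#' error; the bias of the estimated RMST difference against the generator's
#' true [true_delta()] (zero under the null); the Monte-Carlo standard
#' error of that bias, `sd(delta_hat) / sqrt(n_used)`; and the exclusion
#' bookkeeping.
#'
#' Replications where an estimator is undefined (nonparametric) or
#' inestimable (parametric) are excluded for that estimator. In addition,
#' when a nonparametric method is part of the scenario, parametric rejection
#' rates and bias are computed only on replications where the nonparametric
#' estimator is defined at that truncation time, keeping the comparison
#' across methods fair; these fairness exclusions are reported separately.
#'
#' @param config A [scenario_config()].
#' @param progress Print a progress line every 500 replications.
#' @return A `sweep_result` data frame with one row per (method, t_star) and
#'   columns `method`, `t_star`, `rejection_rate`, `mc_se`, `bias`,
#'   `mcse_bias`, `mean_delta`, `mean_se`, `n_used`, `n_excluded`,
#'   `n_excluded_fair`, `usable`.
#' @export
operating_characteristics <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  gen <- effective_generator(config)
  tgrid <- config$t_star
  nt <- length(tgrid)
  nrep <- config$n_reps
  seeds <- rep_seeds(config$seed, nrep)
  truth <- if (config$hypothesis == "null") rep(0, nt)
           else true_delta(config$generator, tgrid, config$prevalence)$delta

  mnames <- names(config$methods)
  delta <- se <- lapply(mnames, function(.) matrix(NA_real_, nrep, nt))
  defined <- lapply(mnames, function(.) matrix(FALSE, nrep, nt))
  names(delta) <- names(se) <- names(defined) <- mnames

  for (i in seq_len(nrep)) {
    table <- simulate_trial(gen, config$n_subjects, config$censoring,
                            config$prevalence, seed = seeds[i])
    res <- evaluate_table(table, config)
    for (m in mnames) {
      delta[[m]][i, ] <- res[[m]]$delta
      se[[m]][i, ] <- res[[m]]$se
      defined[[m]][i, ] <- res[[m]]$defined
    }
    if (progress && i %% 500 == 0)
      message("replication ", i, " of ", nrep)
  }

  np <- mnames[vapply(config$methods, `[[`, "", "type") == "nonparametric"]
  np_ok <- if (length(np)) defined[[np[1]]] else NULL
  zcrit <- stats::qnorm(1 - config$alpha)

  rows <- lapply(mnames, function(m) {
    parametric <- config$methods[[m]]$type == "parametric"
    own <- defined[[m]]
    used <- if (parametric && !is.null(np_ok)) own & np_ok else own
    vapply(seq_len(nt), function(j) {
      u <- used[, j]
      nu <- sum(u)
      if (nu == 0)
        return(c(rejection_rate = NA, mc_se = NA, bias = NA, mcse_bias = NA,
                 mean_delta = NA, mean_se = NA, n_used = 0,
                 n_excluded = nrep - sum(own[, j]),
                 n_excluded_fair = sum(own[, j]) - 0, usable = 0))
      d <- delta[[m]][u, j]
      s <- se[[m]][u, j]
      p <- mean(ifelse(s > 0, d / s, 0) > zcrit)
      c(rejection_rate = p,
        mc_se = sqrt(p * (1 - p) / nu),
        bias = mean(d) - truth[j],
        mcse_bias = if (nu > 1) stats::sd(d) / sqrt(nu) else NA_real_,
        mean_delta = mean(d), mean_se = mean(s),
        n_used = nu,
        n_excluded = nrep - sum(own[, j]),
        n_excluded_fair = sum(own[, j]) - nu,
        usable = 1)
    }, numeric(10))
  })
  out <- do.call(rbind, lapply(seq_along(mnames), function(k)
    data.frame(method = mnames[k], t_star = tgrid, t(rows[[k]]))))
  out$usable <- out$usable == 1
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "hypothesis") <- config$hypothesis
  attr(out, "n_reps") <- nrep
  out
}

#' Truncation-time sweep
#'
#' Evaluates the configured methods over a grid of truncation times. All
#' grid points reuse the same simulated replications (estimators are
#' re-evaluated per `t*`), which removes between-point simulation noise.
#'
#' @param config A [scenario_config()].
#' @param t_grid Truncation times in weeks.
#' @inheritParams operating_characteristics
#' @return A `sweep_result` data frame (see [operating_characteristics()]).
#' @export
sweep_t_star <- function(config, t_grid = config$t_star, progress = FALSE) {
  config$t_star <- as.numeric(t_grid)
  operating_characteristics(config, progress)
}

#' Sex-coefficient sweep
#'
#' Re-runs the scenario for each value of the sex coefficient in the
#' generating model (both intervals), evaluating at a single truncation
#' time. Each grid point gets its own derived seed, so points are
#' independent but the whole sweep is reproducible from the master seed.
#'
#' @param config A [scenario_config()].
#' @param beta3_grid Sex-coefficient values on the log-hazard scale.
#' @param t_star Single truncation time in weeks.
#' @inheritParams operating_characteristics
#' @return A `sweep_result` with an additional `beta3` column.
#' @export
sweep_beta3 <- function(config, beta3_grid, t_star, progress = FALSE) {
  stopifnot(length(t_star) == 1)
  set.seed(config$seed)
  subseeds <- sample.int(2147483646L, length(beta3_grid))
  out <- lapply(seq_along(beta3_grid), function(g) {
    cfg <- config
    cfg$generator$beta_a["sex"] <- beta3_grid[g]
    cfg$generator$beta_b["sex"] <- beta3_grid[g]
    cfg$t_star <- t_star
    cfg$seed <- subseeds[g]
    r <- operating_characteristics(cfg, progress)
    r$beta3 <- beta3_grid[g]
    r
  })
  out <- do.call(rbind, out)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Fitted-knot sweep
#'
#' Evaluates parametric variants whose fitted knot runs over a grid while
#' the generating model keeps its true knot, at a single truncation time.
#' All knot values are fitted to the same simulated replications, and a
#' nonparametric reference is carried along when present in `config`.
#'
#' @param config A [scenario_config()]; its first parametric method acts as
#'   the template (covariate subset) for the knot variants.
#' @param knot_grid Fitted knot times in weeks.
#' @param t_star Single truncation time in weeks.
#' @inheritParams operating_characteristics
#' @return A `sweep_result` with an additional `fitted_knot` column (`NA`
#'   for the nonparametric reference).
#' @export
sweep_knot <- function(config, knot_grid, t_star, progress = FALSE) {
  stopifnot(length(t_star) == 1)
  types <- vapply(config$methods, `[[`, "", "type")
  template <- config$methods[types == "parametric"][1]
  if (!length(template) || is.na(names(template)))
    stop("'config' must contain a parametric method to act as template")
  template <- template[[1]]
  methods <- list()
  if (any(types == "nonparametric"))
    methods <- config$methods[types == "nonparametric"][1]
  for (k in knot_grid)
    methods[[paste0("knot_", format(k))]] <-
      method_parametric(paste0("knot_", format(k)),
                        covariates = template$covariates, knot = k)
  cfg <- config
  cfg$methods <- methods
  cfg$t_star <- t_star
  out <- operating_characteristics(cfg, progress)
  out$fitted_knot <- NA_real_
  is_knot <- grepl("^knot_", out$method)
  out$fitted_knot[is_knot] <- as.numeric(sub("^knot_", "",
                                             out$method[is_knot]))
  out
}
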