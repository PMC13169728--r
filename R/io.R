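# Configuration files, result serialization and run manifests.
#
# Scenario files are YAML with four sections (model, trial, censoring,
# study); every key is validated and unknown keys are errors, so a typo in a
# scenario file fails loudly instead of silently falling back to a default.

known_keys <- list(
  top = c("description", "model", "trial", "censoring", "study"),
  model = c("lambda_a", "lambda_b", "beta_a", "beta_b", "t1"),
  trial = c("n_subjects", "prevalence"),
  censoring = c("random_rate", "accrual_window", "study_end"),
  study = c("hypothesis", "t_star", "n_reps", "seed", "alpha", "methods",
            "sweep"),
  method = c("name", "type", "covariates", "knot"),
  sweep = c("kind", "grid", "t_star"))

check_keys <- function(x, section, path) {
  unknown <- setdiff(names(x), known_keys[[section]])
  if (length(unknown))
    stop("unknown key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
}

expand_grid_spec <- function(x, what) {
  if (is.list(x) && all(c("from", "to") %in% names(x))) {
    by <- if (is.null(x$by)) 1 else x$by
    seq(x$from, x$to, by = by)
  } else if (is.numeric(x) || is.list(x)) {
    as.numeric(unlist(x))
  } else stop("cannot interpret ", what, " specification")
}

#' Read a scenario configuration file
#'
#' Parses and validates a YAML scenario file into a [scenario_config()]
#' (plus an optional sweep request). The file has sections `model`
#' (`lambda_a`, `lambda_b`, `beta_a`, `beta_b`, `t1`), `trial`
#' (`n_subjects`, `prevalence`), `censoring` (`random_rate`,
#' `accrual_window`, `study_end`) and `study` (`hypothesis`, `t_star` —
#' either a list of values or `{from, to, by}` —, `n_reps`, `seed`,
#' `alpha`, `methods`, and optionally `sweep`). Unknown keys anywhere are
#' errors. Packaged presets live under
#' `system.file("extdata", "presets", package = "rmstcomb")`.
#'
#' @param path Path to a YAML scenario file.
#' @return A `scenario_config` with attributes `sweep` (list or `NULL`) and
#'   `description`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, "top", path)
  for (sec in c("model", "trial", "study"))
    if (is.null(raw[[sec]])) stop("missing section '", sec, "' in ", path)
  check_keys(raw$model, "model", path)
  check_keys(raw$trial, "trial", path)
  check_keys(raw$study, "study", path)
  if (!is.null(raw$censoring)) check_keys(raw$censoring, "censoring", path)

  m <- raw$model
  params <- pwe_params(m$lambda_a, m$lambda_b, as.numeric(unlist(m$beta_a)),
                       as.numeric(unlist(m$beta_b)),
                       t1 = if (is.null(m$t1)) 0 else m$t1)
  cens <- do.call(censoring_config,
                  if (is.null(raw$censoring)) list() else raw$censoring)
  methods <- lapply(raw$study$methods, function(mm) {
    check_keys(mm, "method", path)
    if (identical(mm$type, "nonparametric")) {
      method_nonparametric(if (is.null(mm$name)) "nonparametric" else mm$name)
    } else if (identical(mm$type, "parametric")) {
      method_parametric(mm$name,
                        covariates = as.character(unlist(mm$covariates)),
                        knot = if (is.null(mm$knot)) 0 else mm$knot)
    } else stop("method type must be 'nonparametric' or 'parametric'")
  })
  sweep <- raw$study$sweep
  if (!is.null(sweep)) {
    check_keys(sweep, "sweep", path)
    if (!sweep$kind %in% c("t_star", "beta3", "knot"))
      stop("sweep kind must be one of t_star, beta3, knot")
    if (sweep$kind != "t_star")
      sweep$grid <- expand_grid_spec(sweep$grid, "sweep grid")
  }
  cfg <- scenario_config(
    generator = params,
    n_subjects = raw$trial$n_subjects,
    censoring = cens,
    t_star = expand_grid_spec(raw$study$t_star, "t_star"),
    methods = methods,
    n_reps = raw$study$n_reps,
    seed = raw$study$seed,
    hypothesis = if (is.null(raw$study$hypothesis)) "alternative"
                 else raw$study$hypothesis,
    prevalence = if (is.null(raw$trial$prevalence)) 0.5
                 else raw$trial$prevalence,
    alpha = if (is.null(raw$study$alpha)) 0.025 else raw$study$alpha)
  attr(cfg, "sweep") <- sweep
  attr(cfg, "description") <- raw$description
  cfg
}

# Canonical representation with recursively sorted keys, so the digest is
# invariant to field order in the file.
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

#' Content digest and run manifest
#'
#' `config_digest()` hashes a resolved configuration after recursively
#' sorting keys (so reordering fields in a scenario file does not change the
#' digest). `run_manifest()` bundles the digest, master seed, timestamp and
#' package version; writing it next to results makes any published table
#' regenerable.
#'
#' @param config A `scenario_config` (or any list-like configuration).
#' @return `config_digest()`: an md5 string. `run_manifest()`: a list.
#' @export
config_digest <- function(config) {
  attributes(config) <- attributes(config)["names"]
  txt <- paste(deparse(canonicalize(unclass(config))), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @rdname config_digest
#' @param seed Master seed recorded in the manifest.
#' @export
run_manifest <- function(config, seed = config$seed) {
  list(config_digest = config_digest(config),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       software_version = as.character(utils::packageVersion("rmstcomb")))
}

#' Write sweep results and manifest
#'
#' Writes a tidy results CSV (one row per scenario grid point and method)
#' and a JSON run manifest alongside it.
#'
#' @param result A `sweep_result` data frame.
#' @param path Output CSV path.
#' @param manifest Optional manifest list from [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, manifest = NULL) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, sub("\\.csv$", "_manifest.json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
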