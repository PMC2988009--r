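# End-to-end orchestration: simulate a cohort, split it, develop models,
# validate them and write report tables. Configuration is one JSON document;
# every random element is governed by explicit seeds, and each run writes a
# manifest (config + seeds + package version) sufficient to reproduce its
# outputs exactly.

#' Build a run configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param methods Methods to develop; default all eight.
#' @param n Cohort size for simulation, default 1066.
#' @param profile_path Optional path to a JSON class profile; default the
#'   packaged cohort profile.
#' @param data_path Optional path to an existing cohort CSV (skips
#'   simulation).
#' @param split_fraction Training fraction, default 0.71.
#' @param seed Master seed; component seeds derive from it.
#' @param bootstrap Bootstrap resamples for validation CIs (0 = none).
#' @param select_runs,tune_folds Selection/tuning effort knobs passed to
#'   \code{\link{polyrisk}}.
#' @param gamma_grid,lambda_grid Regularization grids.
#' @param variables Optional fixed variable list forwarded to
#'   \code{\link{polyrisk}} (bypasses selection for every method).
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(out_dir, methods = POLYRISK_METHODS, n = 1066,
                       profile_path = NULL, data_path = NULL,
                       split_fraction = 0.71, seed = 1, bootstrap = 0,
                       select_runs = 5, tune_folds = 5,
                       gamma_grid = default_gamma_grid(),
                       lambda_grid = default_lambda_grid(),
                       variables = NULL) {
  bad <- setdiff(methods, POLYRISK_METHODS)
  if (length(bad)) stop_("unknown method(s): %s", paste(bad, collapse = ", "))
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_("split_fraction must be in (0,1)")
  if (!is.null(profile_path) && !file.exists(profile_path))
    stop_("profile path does not exist: %s", profile_path)
  if (!is.null(data_path) && !file.exists(data_path))
    stop_("data path does not exist: %s", data_path)
  structure(list(out_dir = out_dir, methods = methods, n = n,
                 profile_path = profile_path, data_path = data_path,
                 split_fraction = split_fraction, seed = seed,
                 bootstrap = bootstrap, select_runs = select_runs,
                 tune_folds = tune_folds, gamma_grid = gamma_grid,
                 lambda_grid = lambda_grid, variables = variables),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with fields as in \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- obj[intersect(names(obj), names(formals(run_config)))]
  do.call(run_config, args)
}

config_profile <- function(config) {
  if (is.null(config$profile_path)) default_class_profile()
  else read_profile(config$profile_path)
}

config_dataset <- function(config) {
  profile <- config_profile(config)
  if (!is.null(config$data_path))
    read_dataset(config$data_path, schema = profile_schema(profile),
                 classes = profile$classes)
  else simulate_cohort(profile, n = config$n, seed = config$seed)
}

write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- c(list(package_version =
                       as.character(utils::packageVersion("polyrisk")),
                     config = unclass(config)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Pipeline commands: simulate, develop, validate, full study replica
#'
#' \code{cmd_simulate} writes the simulated cohort CSV. \code{cmd_develop}
#' splits the cohort, fits the configured methods on the training part and
#' writes model documents. \code{cmd_validate} evaluates stored (or freshly
#' developed) models on the held-out part, writing per-method reports, a
#' polytomous c-index summary table and a pairwise c-index table.
#' \code{cmd_run_all} chains all three. Artifacts are deterministic under
#' the config's seed; every command writes a manifest.
#'
#' @param config A \code{run_config}.
#' @return \code{cmd_simulate}: the dataset path; \code{cmd_develop}: named
#'   list of model paths; \code{cmd_validate}/\code{cmd_run_all}: named
#'   list of report data-frame paths (invisibly returns the reports).
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- config_dataset(config)
  path <- file.path(config$out_dir, "cohort.csv")
  write_dataset(ds, path)
  write_manifest(config, config$out_dir, list(stage = "simulate"))
  path
}

develop_one <- function(config, method, train) {
  polyrisk(train, method = method, variables = config$variables,
           gamma_grid = config$gamma_grid,
           lambda_grid = config$lambda_grid,
           select_runs = config$select_runs,
           tune_folds = config$tune_folds, seed = config$seed)
}

#' @rdname cmd_simulate
#' @export
cmd_develop <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- config_dataset(config)
  sp <- stratified_split(ds, config$split_fraction, seed = config$seed + 1)
  write_dataset(sp$train, file.path(config$out_dir, "train.csv"))
  write_dataset(sp$test, file.path(config$out_dir, "test.csv"))
  paths <- list()
  for (mth in config$methods) {
    m <- develop_one(config, mth, sp$train)
    p <- file.path(config$out_dir, paste0("model_", gsub("-", "_", mth),
                                          ".json"))
    write_model(m, p)
    paths[[mth]] <- p
  }
  write_manifest(config, config$out_dir, list(stage = "develop"))
  paths
}

#' @rdname cmd_simulate
#' @export
cmd_validate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  profile <- config_profile(config)
  test_path <- file.path(config$out_dir, "test.csv")
  if (!file.exists(test_path))
    stop_("no held-out data found under %s; run cmd_develop first",
          config$out_dir)
  test <- read_dataset(test_path, schema = profile_schema(profile),
                       classes = profile$classes)
  reports <- list()
  for (mth in config$methods) {
    p <- file.path(config$out_dir, paste0("model_", gsub("-", "_", mth),
                                          ".json"))
    if (!file.exists(p)) stop_("missing model document: %s", p)
    m <- read_model(p)
    rep <- validate_model(m, test, bootstrap = config$bootstrap,
                          seed = config$seed + 2)
    reports[[mth]] <- rep
    utils::write.csv(report_row(rep),
                     file.path(config$out_dir,
                               paste0("report_", gsub("-", "_", mth),
                                      ".csv")),
                     row.names = FALSE)
    for (e in names(rep$calibration)) {
      if (is.null(rep$calibration[[e]])) next
      utils::write.csv(as.data.frame(rep$calibration[[e]]),
                       file.path(config$out_dir,
                                 paste0("calibration_",
                                        gsub("-", "_", mth), "_", e,
                                        ".csv")),
                       row.names = FALSE)
    }
  }
  tab3 <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, n = r$n,
               polytomous_c = r$polytomous$estimate,
               ci_lower = if (!is.null(r$polytomous$ci))
                 r$polytomous$ci$lower else NA_real_,
               ci_upper = if (!is.null(r$polytomous$ci))
                 r$polytomous$ci$upper else NA_real_)
  }))
  tab4 <- do.call(rbind, lapply(reports, function(r) {
    row <- data.frame(method = r$method)
    for (q in names(r$pairwise)) row[[q]] <- r$pairwise[[q]]$estimate
    row
  }))
  utils::write.csv(tab3, file.path(config$out_dir,
                                   "polytomous_c_index_table.csv"),
                   row.names = FALSE)
  utils::write.csv(tab4, file.path(config$out_dir,
                                   "pairwise_c_index_table.csv"),
                   row.names = FALSE)
  write_manifest(config, config$out_dir, list(stage = "validate"))
  invisible(reports)
}

#' @rdname cmd_simulate
#' @export
cmd_run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cmd_simulate(config)
  config$data_path <- file.path(config$out_dir, "cohort.csv")
  cmd_develop(config)
  cmd_validate(config)
}
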