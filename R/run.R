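# Pipeline runners: validated configs in, files out.  These back the
# command-line front end but are ordinary functions, usable directly.

check_config <- function(config, required, optional) {
  if (!is.list(config)) stop_validation("config must be a list")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop_validation(sprintf("config lacks required keys: %s",
                            paste(missing, collapse = ", ")))
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown))
    stop_validation(sprintf("config has unknown keys: %s",
                            paste(unknown, collapse = ", ")))
  invisible(config)
}

#' MD5 hash of a run configuration
#'
#' Canonical JSON serialization hashed with MD5; stamped into every output
#' log so a run can be traced back to its exact configuration.
#'
#' @param config A configuration list.
#' @return A hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_run_log <- function(path, config, seed) {
  lines <- c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("package: phratefit %s",
            as.character(utils::packageVersion("phratefit"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("config_hash: %s", config_hash(config)))
  writeLines(lines, path)
  invisible(path)
}

config_params <- function(x, default) {
  if (is.null(x)) return(default)
  do.call(rate_params, x)
}

config_noise <- function(x, seed) {
  if (is.null(x)) return(noise_model("none", seed = seed))
  noise_model(kind = if (is.null(x$kind)) "none" else x$kind,
              cv = if (is.null(x$cv)) 0.1 else x$cv, seed = seed)
}

config_design <- function(x) {
  if (is.null(x)) return(experiment_design())
  args <- x[intersect(names(x), c("pH_grid", "cat_grid", "times",
                                  "n_times", "half_lives", "replicates"))]
  do.call(experiment_design, args)
}

#' Simulate a full synthetic experiment to disk
#'
#' Generates a catalyst-free and a with-catalyst pH-rate profile, a
#' catalyst-concentration series and an HPLC-style time course from
#' ground-truth parameters, and writes them as CSV files together with a
#' ground-truth JSON sidecar and a run log.
#'
#' Config keys: `out_dir`, `seed` (required); `truth` (optional list with
#' `background` and `catalyst` parameter sublists; defaults to
#' [ref_rate_params()]), `cat_conc` (profile catalyst concentration,
#' default 1e-3 M), `pH` (series pH, default 7), `design`, `noise`
#' (`kind`, `cv`), `network` (rate-constant sublist), `conditions`.
#'
#' @param config Configuration list (unknown keys are rejected).
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_simulate <- function(config) {
  check_config(config, required = c("out_dir", "seed"),
               optional = c("truth", "cat_conc", "pH", "design", "noise",
                            "network", "conditions"))
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth_bg <- config_params(config$truth$background, ref_rate_params(FALSE))
  truth_cat <- config_params(config$truth$catalyst, ref_rate_params(TRUE))
  cat_conc <- if (is.null(config$cat_conc)) 1e-3 else config$cat_conc
  pH_series <- if (is.null(config$pH)) 7 else config$pH
  design <- config_design(config$design)
  net <- if (is.null(config$network)) {
    k_cl <- cleavage_rate(truth_cat, pH_series, cat_conc)
    # unprinted network constants: assumed magnitudes of the same order as
    # the cleavage rate (see the truth sidecar's "assumptions" block)
    kinetic_network(k_iso_45 = 0.5 * k_cl, k_iso_54 = 0.5 * k_cl,
                    k_cl_4 = k_cl, k_h_cAMP = 2 * k_cl, k_h_AMP = k_cl)
  } else {
    do.call(kinetic_network, config$network)
  }

  paths <- c(profile_background = file.path(out_dir,
                                            "profile_background.csv"),
             profile_catalyst = file.path(out_dir, "profile_catalyst.csv"),
             conc_series = file.path(out_dir, "conc_series.csv"),
             timecourse = file.path(out_dir, "timecourse.csv"),
             truth = file.path(out_dir, "truth.json"),
             log = file.path(out_dir, "run.log"))

  write_ph_profile(
    gen_ph_profile(truth_bg, design, 0, config_noise(config$noise, seed)),
    paths[["profile_background"]])
  write_ph_profile(
    gen_ph_profile(truth_cat, design, cat_conc,
                   config_noise(config$noise, seed + 1L)),
    paths[["profile_catalyst"]])
  write_conc_series(
    gen_conc_series(truth_cat, design, pH_series,
                    config_noise(config$noise, seed + 2L)),
    paths[["conc_series"]])
  write_timecourse(
    gen_timecourse(net, design, config_noise(config$noise, seed + 3L)),
    paths[["timecourse"]])

  truth <- list(
    background = unclass(truth_bg), catalyst = unclass(truth_cat),
    cat_conc = cat_conc, pH_series = pH_series,
    network = unclass(net),
    assumptions = paste("isomerization and cAMP/AMP hydrolysis rate",
                        "constants are assumed magnitudes, not measured",
                        "values"),
    noise = if (is.null(config$noise)) list(kind = "none")
            else config$noise,
    seed = seed)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             paths[["truth"]])
  write_run_log(paths[["log"]], config, seed)
  invisible(paths)
}

#' Fit the pH-rate law to profile CSV files
#'
#' Config keys: `input` (one or more profile CSV paths), `out_dir`
#' (required); `cat_conc` (vector matching `input`, default all 0), `KW`,
#' `fix`, `start`.  Writes `fit_profile.json`, a human-readable
#' `fit_profile.txt` report, and a run log.  A non-converged optimization
#' raises a numerical-failure condition after writing diagnostics.
#'
#' @param config Configuration list.
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_fit_profile <- function(config) {
  check_config(config, required = c("input", "out_dir"),
               optional = c("cat_conc", "KW", "fix", "start", "seed"))
  inputs <- as.character(config$input)
  cat_conc <- if (is.null(config$cat_conc)) rep(0, length(inputs))
              else rep_len(as.numeric(config$cat_conc), length(inputs))
  profiles <- Map(read_ph_profile, inputs, cat_conc)
  KW <- if (is.null(config$KW)) 6.2e-13 else config$KW
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(out_dir, "fit_profile.json"),
             report = file.path(out_dir, "fit_profile.txt"),
             log = file.path(out_dir, "run.log"))

  fit <- fit_ph_profile(unname(profiles), fix = config$fix,
                        start = config$start, KW = KW)
  payload <- list(
    estimates = unclass(fit$estimates),
    free = fit$free, se = as.list(fit$se),
    converged = fit$converged, info = fit$info, message = fit$message,
    objective = fit$objective,
    na = setdiff(c("kcat", "Ka"), fit$free))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             paths[["json"]])
  write_run_log(paths[["log"]], config, config$seed)
  if (!fit$converged)
    stop_numerical(sprintf("fit did not converge (info %d): %s",
                           fit$info, fit$message))
  report <- profile_report(fit)
  writeLines(format(report), paths[["report"]])
  invisible(paths)
}

#' Fit a catalyst-concentration series from CSV
#'
#' Config keys: `input`, `out_dir` (required); `pH` (default 7),
#' `speciation_correction` (logical), `Ka` (required when the correction
#' is requested).  Writes `fit_conc.json` (slope, intercept, fold-
#' acceleration column) and a run log.
#'
#' @param config Configuration list.
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_fit_conc <- function(config) {
  check_config(config, required = c("input", "out_dir"),
               optional = c("pH", "speciation_correction", "Ka", "seed"))
  pH <- if (is.null(config$pH)) 7 else config$pH
  series <- read_conc_series(config$input, pH = pH)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- fit_conc_series(series,
                         speciation_correction =
                           isTRUE(config$speciation_correction),
                         Ka = config$Ka)
  paths <- c(json = file.path(out_dir, "fit_conc.json"),
             log = file.path(out_dir, "run.log"))
  payload <- list(
    pH = pH, slope = fit$slope, intercept = fit$intercept,
    se_slope = fit$se_slope, se_intercept = fit$se_intercept,
    kcat_intrinsic = fit$kcat_intrinsic,
    speciation_fraction = fit$speciation_fraction,
    fold_acceleration = data.frame(cat_conc = series$cat_conc,
                                   fold = fit$fold))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE,
                              dataframe = "columns"),
             paths[["json"]])
  write_run_log(paths[["log"]], config, config$seed)
  invisible(paths)
}
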