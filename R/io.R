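#' Read and write pH-rate profile CSV files
#'
#' The on-disk dialect is a UTF-8 comma-separated file with header
#' `pH,k_obs_per_s,se_per_s`.  The catalyst concentration is not part of
#' the file and must be supplied (it normally travels in the run
#' configuration or the ground-truth sidecar).
#'
#' @param path File path.
#' @param cat_conc Catalyst concentration (M) to attach on read.
#' @return `read_ph_profile` returns a [ph_profile];
#'   `write_ph_profile` returns `path` invisibly.
#' @export
read_ph_profile <- function(path, cat_conc = 0) {
  df <- read_csv_checked(path, c("pH", "k_obs_per_s", "se_per_s"))
  ph_profile(df$pH, df$k_obs_per_s, df$se_per_s, cat_conc = cat_conc)
}

#' @param profile A [ph_profile] to write.
#' @rdname read_ph_profile
#' @export
write_ph_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ph_profile"))
  df <- data.frame(pH = profile$pH, k_obs_per_s = profile$k_obs,
                   se_per_s = profile$se)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write catalyst-concentration series CSV files
#'
#' Dialect: header `cat_conc_M,k_obs_per_s,se_per_s`, comma-separated.
#'
#' @param path File path.
#' @param pH Fixed pH of the series, attached on read.
#' @return `read_conc_series` returns a [conc_series];
#'   `write_conc_series` returns `path` invisibly.
#' @export
read_conc_series <- function(path, pH = 7) {
  df <- read_csv_checked(path, c("cat_conc_M", "k_obs_per_s", "se_per_s"))
  conc_series(df$cat_conc_M, df$k_obs_per_s, df$se_per_s, pH = pH)
}

#' @param series A [conc_series] to write.
#' @rdname read_conc_series
#' @export
write_conc_series <- function(series, path) {
  stopifnot(inherits(series, "conc_series"))
  df <- data.frame(cat_conc_M = series$cat_conc,
                   k_obs_per_s = series$k_obs, se_per_s = series$se)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write time-course CSV files
#'
#' Dialect: header
#' `time_s,frac_4,frac_5,frac_6,frac_cAMP,frac_AMP,frac_Ado`, one row per
#' aliquot.
#'
#' @param path File path.
#' @return `read_timecourse` returns a `time_course`;
#'   `write_timecourse` returns `path` invisibly.
#' @export
read_timecourse <- function(path) {
  df <- read_csv_checked(path, c("time_s", network_species()))
  time_course(df$time_s, df[network_species()])
}

#' @param tc A `time_course` to write.
#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, expected) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(expected %in% names(df)))
    stop_data(sprintf("'%s' lacks required columns: %s", path,
                      paste(setdiff(expected, names(df)), collapse = ", ")))
  df
}
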