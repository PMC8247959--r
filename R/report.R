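#' Structured report of a pH-rate profile fit
#'
#' Collects the fitted parameters in the conventional scaled units of the
#' field (kH in 10^-3 M^-1 s^-1, kH2O in 10^-7 s^-1, kOH in M^-1 s^-1,
#' kcat in 10^-3 M^-1 s^-1, Ka in 10^-6 M), the per-point predicted versus
#' observed rate constants, and the fold acceleration implied by the fitted
#' law for the with-catalyst data.  Parameters absent from the fit (kcat
#' and Ka when no catalyst data were supplied) are marked `"n.a."`.
#'
#' @param fit A converged `ph_fit` from [fit_ph_profile()].
#' @param profiles The profiles that were fitted (optional; defaults to the
#'   data stored in the fit).
#' @return An object of class `cleavage_report`: list with `param_table`
#'   (data frame with numeric `value`, `se`, `scale` and formatted
#'   `display` columns), `predictions`, `acceleration`, and the `estimates`
#'   themselves.
#' @export
profile_report <- function(fit, profiles = NULL) {
  stopifnot(inherits(fit, "ph_fit"))
  if (!fit$converged)
    stop_numerical("cannot report an unconverged fit")
  est <- fit$estimates
  scales <- c(kH = 1e-3, kH2O = 1e-7, kOH = 1, kcat = 1e-3, Ka = 1e-6)
  units <- c(kH = "10^-3 M^-1 s^-1", kH2O = "10^-7 s^-1",
             kOH = "M^-1 s^-1", kcat = "10^-3 M^-1 s^-1", Ka = "10^-6 M")
  nm <- names(scales)
  val <- vapply(nm, function(n) {
    v <- est[[n]]
    if (n %in% fit$free) v else NA_real_
  }, numeric(1))
  se <- vapply(nm, function(n) {
    if (n %in% names(fit$se)) fit$se[[n]] else NA_real_
  }, numeric(1))
  fmt <- function(x, s) {
    if (is.na(x)) "n.a." else formatC(signif(x / s, 2), format = "fg")
  }
  param_table <- data.frame(
    parameter = nm, units = unname(units), scale = unname(scales),
    value = unname(val), se = unname(se),
    value_scaled = unname(val / scales), se_scaled = unname(se / scales),
    display = vapply(nm, function(n) fmt(val[[n]], scales[[n]]),
                     character(1)),
    row.names = NULL)
  dat <- fit$data
  predictions <- data.frame(pH = dat$pH, cat_conc = dat$cat_conc,
                            k_obs = dat$k_obs, k_pred = fit$fitted,
                            residual_log10 = log10(fit$fitted) -
                              log10(dat$k_obs))
  cat_rows <- dat$cat_conc > 0
  acceleration <- if (any(cat_rows)) {
    data.frame(pH = dat$pH[cat_rows], cat_conc = dat$cat_conc[cat_rows],
               fold = fit$fitted[cat_rows] /
                 cleavage_rate(est, dat$pH[cat_rows], 0))
  } else {
    data.frame(pH = numeric(0), cat_conc = numeric(0), fold = numeric(0))
  }
  structure(list(param_table = param_table, predictions = predictions,
                 acceleration = acceleration, estimates = est,
                 objective = fit$objective, converged = fit$converged),
            class = "cleavage_report")
}

#' Reconstruct rate-law parameters from a report
#'
#' Inverse of the tabulation in [profile_report()]: rebuilds a
#' [rate_params] object from the numeric columns of the parameter table, so
#' that report and parameters round-trip exactly.
#'
#' @param report A `cleavage_report`.
#' @param KW Ionic product of water to carry (M^2).
#' @return A [rate_params] object identical to `report$estimates` for the
#'   fitted parameters.
#' @export
params_from_report <- function(report, KW = 6.2e-13) {
  stopifnot(inherits(report, "cleavage_report"))
  tb <- report$param_table
  g <- function(n) {
    v <- tb$value[tb$parameter == n]
    if (is.na(v)) if (n == "Ka") NA_real_ else 0 else v
  }
  rate_params(kH = g("kH"), kH2O = g("kH2O"), kOH = g("kOH"),
              kcat = g("kcat"), Ka = g("Ka"), KW = KW)
}

#' @export
print.cleavage_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.cleavage_report <- function(x, ...) {
  tb <- x$param_table
  lines <- c("Rate and kinetic acid dissociation constants",
             "--------------------------------------------")
  for (i in seq_len(nrow(tb))) {
    lines <- c(lines, sprintf("  %-5s /%-16s %s%s", tb$parameter[i],
                              tb$units[i], tb$display[i],
                              if (!is.na(tb$se_scaled[i]))
                                sprintf(" +/- %s",
                                        formatC(signif(tb$se_scaled[i], 2),
                                                format = "fg"))
                              else ""))
  }
  if (nrow(x$acceleration)) {
    imax <- which.max(x$acceleration$fold)
    lines <- c(lines, sprintf(
      "  max fold acceleration %.2g at pH %.2f (%.3g M catalyst)",
      x$acceleration$fold[imax], x$acceleration$pH[imax],
      x$acceleration$cat_conc[imax]))
  }
  lines
}
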