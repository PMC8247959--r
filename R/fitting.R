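#' Construct a pH-rate profile
#'
#' Observed cleavage rate constants as a function of pH at a fixed catalyst
#' concentration, with per-point standard errors.
#'
#' @param pH Numeric vector of distinct pH values.
#' @param k_obs Observed rate constants (s^-1), > 0.
#' @param se Standard errors of `k_obs` (s^-1); 0 means unknown/exact, in
#'   which case fits fall back to unit weights.
#' @param cat_conc Catalyst concentration (M) common to the profile.
#' @param conditions Optional [conditions]-style metadata list.
#' @return A data frame of class `ph_profile` with attributes `cat_conc`
#'   and `conditions`.
#' @export
ph_profile <- function(pH, k_obs, se = 0, cat_conc = 0, conditions = NULL) {
  se <- rep_len(as.numeric(se), length(pH))
  if (length(k_obs) != length(pH))
    stop_validation("'pH' and 'k_obs' differ in length")
  if (anyDuplicated(pH)) stop_validation("'pH' values must be distinct")
  if (any(k_obs <= 0)) stop_validation("'k_obs' must be > 0")
  if (any(se < 0)) stop_validation("'se' must be >= 0")
  if (length(cat_conc) != 1L || cat_conc < 0)
    stop_validation("'cat_conc' must be a single value >= 0")
  out <- data.frame(pH = as.numeric(pH), k_obs = as.numeric(k_obs), se = se)
  attr(out, "cat_conc") <- as.numeric(cat_conc)
  attr(out, "conditions") <- conditions
  class(out) <- c("ph_profile", "data.frame")
  out
}

#' Construct a catalyst-concentration series
#'
#' Observed cleavage rate constants as a function of catalyst concentration
#' at fixed pH.
#'
#' @param cat_conc Numeric vector of distinct catalyst concentrations (M).
#' @param k_obs Observed rate constants (s^-1), > 0.
#' @param se Standard errors of `k_obs` (s^-1).
#' @param pH The fixed pH of the series.
#' @return A data frame of class `conc_series` with attribute `pH`.
#' @export
conc_series <- function(cat_conc, k_obs, se = 0, pH = 7) {
  se <- rep_len(as.numeric(se), length(cat_conc))
  if (length(k_obs) != length(cat_conc))
    stop_validation("'cat_conc' and 'k_obs' differ in length")
  if (anyDuplicated(cat_conc))
    stop_validation("'cat_conc' values must be distinct")
  if (any(cat_conc < 0)) stop_validation("'cat_conc' must be >= 0")
  if (any(k_obs <= 0)) stop_validation("'k_obs' must be > 0")
  out <- data.frame(cat_conc = as.numeric(cat_conc),
                    k_obs = as.numeric(k_obs), se = se)
  attr(out, "pH") <- as.numeric(pH)
  class(out) <- c("conc_series", "data.frame")
  out
}

# stack one or more profiles into a flat data frame with a cat_conc column
profiles_data <- function(profiles) {
  if (inherits(profiles, "ph_profile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE, "ph_profile")))
    stop_validation("'profiles' must be one or more ph_profile objects")
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(pH = p$pH, k_obs = p$k_obs, se = p$se,
               cat_conc = attr(p, "cat_conc"))
  }))
}

# weighted sum of squared log10 residuals; unit weights unless all se > 0
log_weights <- function(dat) {
  if (all(dat$se > 0)) {
    se_log <- dat$se / (dat$k_obs * log(10))
    1 / se_log^2
  } else {
    rep(1, nrow(dat))
  }
}

#' Least-squares objective of the pH-rate law on given data
#'
#' Weighted sum of squared residuals of log10(k) over one or more profiles
#' for a fixed parameter set; the quantity minimized by [fit_ph_profile()].
#' Exposed for diagnostics and for independent cross-checks (e.g. grid
#' searches) of the optimizer.
#'
#' @param params A [rate_params] object.
#' @param profiles One [ph_profile] or a list of them.
#' @return The scalar objective value.
#' @export
profile_objective <- function(params, profiles) {
  dat <- profiles_data(profiles)
  w <- log_weights(dat)
  pred <- cleavage_rate(params, dat$pH, dat$cat_conc)
  sum(w * (log10(pred) - log10(dat$k_obs))^2)
}

# deterministic starting values from the profile geometry: the acidic limb
# pins kH, the basic limb kOH, the mid-pH floor kH2O, the near-neutral
# excess over the background estimate pins kcat
init_ph_params <- function(dat, KW) {
  h <- 10^(-dat$pH)
  i_acid <- which.min(dat$pH)
  i_base <- which.max(dat$pH)
  kH0 <- max(dat$k_obs[i_acid] / h[i_acid], 1e-12)
  kOH0 <- max(dat$k_obs[i_base] * h[i_base] / KW, 1e-12)
  mid <- dat$pH >= 4.5 & dat$pH <= 6
  kH2O0 <- max(if (any(mid)) min(dat$k_obs[mid]) else min(dat$k_obs), 1e-15)
  Ka0 <- 1e-6
  kcat0 <- 1e-4
  catd <- dat[dat$cat_conc > 0, , drop = FALSE]
  if (nrow(catd)) {
    j <- which.min(abs(catd$pH - 7))
    hj <- 10^(-catd$pH[j])
    bg <- kH0 * hj + kH2O0 + kOH0 * KW / hj
    excess <- (catd$k_obs[j] - bg) / catd$cat_conc[j]
    if (is.finite(excess) && excess > 0) kcat0 <- excess
  }
  c(kH = kH0, kH2O = kH2O0, kOH = kOH0, kcat = kcat0, Ka = Ka0)
}

#' Fit the pH-rate law to observed profiles
#'
#' Nonlinear least squares on log10(k_obs): rate constants span several
#' decades across pH 3-8.5, so residuals on the log scale give each limb of
#' the profile comparable leverage and approximate constant relative error.
#' Points are weighted by their log-scale standard errors when all `se` are
#' positive, and equally otherwise.  Parameters are constrained positive by
#' optimizing their logarithms (Levenberg-Marquardt).  When every profile
#' has `cat_conc = 0`, `kcat` and `Ka` are structurally unidentifiable and
#' are excluded from the free set automatically.
#'
#' @param profiles One [ph_profile] or a list of them (e.g. a catalyst-free
#'   and a with-catalyst profile).
#' @param fix Optional named list of parameters to hold fixed at given
#'   values (e.g. `list(kOH = 0.1)`).
#' @param start Optional named list of starting values for free parameters;
#'   defaults to a deterministic heuristic based on the profile limbs.
#'   Requesting a start for `kcat` or `Ka` with no catalyst data is a
#'   validation error.
#' @param KW Ionic product of water (M^2); default 6.2e-13.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `ph_fit`: list with `estimates` (a
#'   [rate_params]), `se` (named, natural scale), `cov` (natural-scale
#'   covariance of the free parameters), `residuals` (log10 scale),
#'   `fitted`, `data`, `free`, `converged`, `info`, `message`, `objective`.
#'   Standard errors are Gauss-Newton 1-sigma values scaled by the reduced
#'   chi-square.
#' @examples
#' truth <- ref_rate_params()
#' prof <- gen_ph_profile(truth, experiment_design(), cat_conc = 0)
#' fit <- fit_ph_profile(prof)
#' fit$estimates
#' @export
fit_ph_profile <- function(profiles, fix = NULL, start = NULL, KW = 6.2e-13,
                           maxiter = 200) {
  dat <- profiles_data(profiles)
  has_cat <- any(dat$cat_conc > 0)
  all_names <- c("kH", "kH2O", "kOH", "kcat", "Ka")
  if (!has_cat && any(c("kcat", "Ka") %in% names(start)))
    stop_validation(
      "'kcat'/'Ka' are unidentifiable without catalyst data")
  if (!is.null(fix) && !all(names(fix) %in% all_names))
    stop_validation("'fix' contains unknown parameter names")
  free <- setdiff(if (has_cat) all_names else all_names[1:3], names(fix))
  if (nrow(dat) < length(free) + 2L)
    stop_validation("need at least 2 more points than free parameters")

  fixed <- list(kH = 0, kH2O = 0, kOH = 0, kcat = 0, Ka = NA_real_)
  for (nm in names(fix)) fixed[[nm]] <- fix[[nm]]

  init <- init_ph_params(dat, KW)
  if (!is.null(start)) {
    if (!all(names(start) %in% free))
      stop_validation("'start' names must be free parameters")
    for (nm in names(start)) init[[nm]] <- start[[nm]]
  }
  theta0 <- log(init[free])

  w <- log_weights(dat)
  sw <- sqrt(w)
  make_params <- function(theta) {
    p <- fixed
    for (i in seq_along(free)) p[[free[i]]] <- exp(theta[[i]])
    rate_params(kH = p$kH, kH2O = p$kH2O, kOH = p$kOH, kcat = p$kcat,
                Ka = p$Ka, KW = KW)
  }
  resid_fn <- function(theta) {
    pr <- make_params(theta)
    sw * (log10(cleavage_rate(pr, dat$pH, dat$cat_conc)) - log10(dat$k_obs))
  }

  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-14,
                              ptol = 1e-14))
  est <- make_params(fit$par)
  converged <- fit$info %in% 1:4
  p <- length(free)
  n <- nrow(dat)
  resvar <- fit$deviance / max(n - p, 1)
  cov_log <- tryCatch(solve(fit$hessian) * resvar,
                      error = function(e) matrix(NA_real_, p, p))
  kvals <- vapply(free, function(nm) est[[nm]], numeric(1))
  D <- diag(kvals, nrow = p)
  cov_nat <- D %*% cov_log %*% D
  dimnames(cov_nat) <- list(free, free)
  se <- sqrt(pmax(diag(cov_nat), 0))
  names(se) <- free

  structure(list(estimates = est, se = se, cov = cov_nat,
                 residuals = fit$fvec,
                 fitted = cleavage_rate(est, dat$pH, dat$cat_conc),
                 data = dat, free = free, converged = converged,
                 info = fit$info, message = fit$message,
                 objective = fit$deviance),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("pH-rate law fit (%s, objective %.4g, %d points)\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$objective, nrow(x$data)))
  for (nm in x$free)
    cat(sprintf("  %-4s = %.4g +/- %.2g\n", nm, x$estimates[[nm]],
                x$se[[nm]]))
  invisible(x)
}

#' Weighted linear fit of a catalyst-concentration series
#'
#' The rate law is affine in catalyst concentration at fixed pH, so the
#' apparent second-order catalytic rate constant is the slope of the
#' weighted least-squares line of k_obs versus concentration.  With
#' `speciation_correction = TRUE` the slope is divided by the speciation
#' fraction at the series pH to report the intrinsic kcat.
#'
#' @param series A [conc_series] with at least three distinct
#'   concentrations.
#' @param speciation_correction Logical; apply the speciation-fraction
#'   correction (requires `Ka`).
#' @param Ka Kinetic acid dissociation constant (M) used for the
#'   correction.
#' @return An object of class `conc_fit`: list with `slope`, `intercept`,
#'   their standard errors, `cov`, `residuals`, `fold` (fitted fold
#'   acceleration relative to the fitted zero-catalyst rate), `converged`,
#'   `objective`, `pH`, and `kcat_intrinsic` when the correction is
#'   applied.
#' @export
fit_conc_series <- function(series, speciation_correction = FALSE,
                            Ka = NULL) {
  stopifnot(inherits(series, "conc_series"))
  if (nrow(series) < 3L)
    stop_validation("at least 3 distinct concentrations are required")
  w <- if (all(series$se > 0)) 1 / series$se^2 else rep(1, nrow(series))
  df <- data.frame(k_obs = series$k_obs, cat_conc = series$cat_conc, w = w)
  fit <- stats::lm(k_obs ~ cat_conc, data = df, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["cat_conc", 1])
  intercept <- unname(co["(Intercept)", 1])
  out <- list(slope = slope, intercept = intercept,
              se_slope = unname(co["cat_conc", 2]),
              se_intercept = unname(co["(Intercept)", 2]),
              cov = stats::vcov(fit),
              residuals = unname(stats::residuals(fit)),
              fold = unname(stats::fitted(fit)) / intercept,
              converged = TRUE,
              objective = sum(w * stats::residuals(fit)^2),
              pH = attr(series, "pH"))
  if (isTRUE(speciation_correction)) {
    if (is.null(Ka)) stop_validation("'Ka' is required for the correction")
    f <- speciation_fraction(Ka, hydronium_conc(out$pH))
    out$kcat_intrinsic <- slope / f
    out$speciation_fraction <- f
  }
  structure(out, class = "conc_fit")
}

#' @export
print.conc_fit <- function(x, ...) {
  cat(sprintf("concentration-series fit at pH %.2f\n", x$pH))
  cat(sprintf("  slope     = %.4g +/- %.2g M^-1 s^-1\n", x$slope,
              x$se_slope))
  cat(sprintf("  intercept = %.4g +/- %.2g s^-1\n", x$intercept,
              x$se_intercept))
  if (!is.null(x$kcat_intrinsic))
    cat(sprintf("  intrinsic kcat = %.4g M^-1 s^-1 (speciation fraction %.3f)\n",
                x$kcat_intrinsic, x$speciation_fraction))
  invisible(x)
}
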