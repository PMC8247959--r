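#' Observation-noise model
#'
#' Noise applied to synthetic observations.  Rate constants and HPLC peak
#' areas are positive with roughly constant relative error, so the
#' stochastic model is multiplicative lognormal: each observation is
#' multiplied by a lognormal factor with unit mean and coefficient of
#' variation `cv`.
#'
#' @param kind `"none"` or `"multiplicative-lognormal"`.
#' @param cv Relative standard deviation of the noise factor (unitless).
#' @param seed Optional integer seed; generators that receive a seeded
#'   model produce identical output on repeated calls.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative-lognormal"),
                        cv = 0.1, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0)
    stop_validation("'cv' must be a single value >= 0")
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L))
    stop_validation("'seed' must be a single integer")
  structure(list(kind = kind, cv = cv,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

# unit-mean lognormal factors; seeds the RNG if the model carries a seed
noise_factors <- function(noise, n) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$cv == 0) return(rep(1, n))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  sdlog <- sqrt(log1p(noise$cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Experiment design for synthetic data
#'
#' Grids and schedules emulating the kinetic experiments: pH-rate profiles
#' over pH 3.0-8.5 in steps of 0.5, catalyst-concentration series over
#' 0-7 mM in 1 mM steps, and HPLC aliquot schedules of 8 points spanning
#' about three half-lives of the starting material.
#'
#' @param pH_grid Numeric vector of pH values.
#' @param cat_grid Numeric vector of catalyst concentrations (M).
#' @param times Optional explicit sampling times (s) for time courses;
#'   when `NULL` a logarithmic schedule is derived from the network.
#' @param n_times Number of aliquots when `times` is derived.
#' @param half_lives Number of pool half-lives the derived schedule spans.
#' @param replicates Replicate count carried as metadata.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(pH_grid = seq(3, 8.5, by = 0.5),
                              cat_grid = seq(0, 7e-3, by = 1e-3),
                              times = NULL, n_times = 8, half_lives = 3,
                              replicates = 1) {
  if (!length(pH_grid) || any(pH_grid < 0) || any(pH_grid > 14))
    stop_validation("'pH_grid' must be nonempty within [0, 14]")
  if (!length(cat_grid) || any(cat_grid < 0))
    stop_validation("'cat_grid' must be nonempty and >= 0")
  if (n_times < 4) stop_validation("'n_times' must be at least 4")
  structure(list(pH_grid = as.numeric(pH_grid),
                 cat_grid = as.numeric(cat_grid), times = times,
                 n_times = as.integer(n_times), half_lives = half_lives,
                 replicates = as.integer(replicates)),
            class = "experiment_design")
}

#' Generate a synthetic pH-rate profile
#'
#' Evaluates the rate law on the design's pH grid at the given catalyst
#' concentration and applies the noise model.  The reported standard error
#' of each point is `cv * k_obs`, mimicking relative uncertainties of
#' HPLC-derived rate constants.
#'
#' @param truth Ground-truth [rate_params].
#' @param design An [experiment_design].
#' @param cat_conc Catalyst concentration (M) of the profile.
#' @param noise A [noise_model].
#' @return A [ph_profile].
#' @examples
#' gen_ph_profile(ref_rate_params(TRUE), cat_conc = 1e-3,
#'                noise = noise_model("multiplicative-lognormal", seed = 1))
#' @export
gen_ph_profile <- function(truth, design = experiment_design(),
                           cat_conc = 0, noise = noise_model("none")) {
  stopifnot(inherits(truth, "rate_params"),
            inherits(design, "experiment_design"))
  k <- cleavage_rate(truth, design$pH_grid, cat_conc)
  f <- noise_factors(noise, length(k))
  k_obs <- k * f
  ph_profile(design$pH_grid, k_obs, se = noise$cv * k_obs,
             cat_conc = cat_conc)
}

#' Generate a synthetic catalyst-concentration series
#'
#' @param truth Ground-truth [rate_params] (with catalytic term).
#' @param design An [experiment_design] providing the concentration grid.
#' @param pH Fixed pH of the series.
#' @param noise A [noise_model].
#' @return A [conc_series].
#' @export
gen_conc_series <- function(truth, design = experiment_design(), pH = 7,
                            noise = noise_model("none")) {
  stopifnot(inherits(truth, "rate_params"),
            inherits(design, "experiment_design"))
  k <- cleavage_rate(truth, rep(pH, length(design$cat_grid)),
                     design$cat_grid)
  f <- noise_factors(noise, length(k))
  k_obs <- k * f
  conc_series(design$cat_grid, k_obs, se = noise$cv * k_obs, pH = pH)
}

# default aliquot schedule: first point at t = 0, then logarithmically
# spaced out to `half_lives` half-lives of the fastest relevant process
schedule_times <- function(network, design) {
  if (!is.null(design$times)) {
    tt <- as.numeric(design$times)
    if (tt[1] != 0 || is.unsorted(tt, strictly = TRUE))
      stop_validation("'times' must be strictly increasing and start at 0")
    return(tt)
  }
  k_pool <- (network$k_cl_4 + network$k_cl_5) / 2
  k_ref <- if (k_pool > 0) k_pool else network$k_iso_45 + network$k_iso_54
  if (k_ref <= 0) return(seq(0, design$n_times - 1))
  t_end <- design$half_lives * log(2) / k_ref
  c(0, exp(seq(log(t_end / 30), log(t_end),
               length.out = design$n_times - 1)))
}

#' Generate a synthetic HPLC time course
#'
#' Propagates the reaction network exactly, then applies multiplicative
#' noise per species and time point and renormalizes each aliquot so that
#' the dimer-equivalent mole fractions sum to one, mimicking composition
#' expressed as HPLC peak-area shares (the methyleneadenosine column is
#' rescaled by the same per-row factor).
#'
#' @param network A [kinetic_network].
#' @param design An [experiment_design]; its `times` (or derived schedule)
#'   set the aliquot times.
#' @param noise A [noise_model].
#' @param initial Starting mole fractions (default: pure 3',5'-dimer).
#' @return A `time_course`.
#' @export
gen_timecourse <- function(network, design = experiment_design(),
                           noise = noise_model("none"),
                           initial = c(1, 0, 0, 0, 0, 0)) {
  stopifnot(inherits(network, "kinetic_network"),
            inherits(design, "experiment_design"))
  times <- schedule_times(network, design)
  tc <- propagate(network, initial, times)
  if (noise$kind == "none" || noise$cv == 0) return(tc)
  frac <- as.matrix(as.data.frame(tc)[network_species()])
  f <- matrix(noise_factors(noise, length(frac)), nrow(frac), ncol(frac))
  noisy <- frac * f
  s <- 1 / rowSums(noisy[, .conserved_cols, drop = FALSE])
  noisy <- noisy * s
  time_course(tc$time_s, noisy)
}
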