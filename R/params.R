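#' Rate-law parameter set for phosphodiester cleavage
#'
#' Container for the rate and kinetic acidity constants of the four-term
#' pH-rate law used throughout the package: hydronium-, water- and
#' hydroxide-promoted background cleavage plus an organometallic catalytic
#' term gated by a diprotic speciation equilibrium.  The two kinetic acid
#' dissociation constants of the catalytic term cannot be resolved
#' independently from the shape of the profile, so a single shared constant
#' `Ka` (Ka1 = Ka2) is carried.
#'
#' @param kH Second-order rate constant for the hydronium-ion-catalyzed
#'   cleavage (M^-1 s^-1).
#' @param kH2O First-order rate constant for the pH-independent (water)
#'   cleavage (s^-1).
#' @param kOH Second-order rate constant for the hydroxide-ion-catalyzed
#'   cleavage (M^-1 s^-1).
#' @param kcat Second-order rate constant for the catalyzed cleavage
#'   (M^-1 s^-1).
#' @param Ka Shared kinetic acid dissociation constant of the catalytic
#'   term (M).  May be `NA` when `kcat = 0`; must be positive otherwise.
#' @param KW Ionic product of water at the experimental conditions (M^2).
#'   The default, 6.2e-13 M^2, corresponds to 90 degrees C and ionic
#'   strength 0.1 M; it is configurable metadata, never a fitted quantity.
#'
#' @return An object of class `rate_params`: a named list with the six
#'   fields above.
#' @examples
#' p <- rate_params(kH = 2.4e-3, kH2O = 1.3e-7, kOH = 0.10)
#' cleavage_rate(p, pH = 7)
#' @export
rate_params <- function(kH = 0, kH2O = 0, kOH = 0, kcat = 0,
                        Ka = NA_real_, KW = 6.2e-13) {
  num1 <- function(x, nm, allow_na = FALSE) {
    if (!is.numeric(x) || length(x) != 1L)
      stop_validation(sprintf("'%s' must be a single numeric value", nm))
    if (is.na(x)) {
      if (!allow_na) stop_validation(sprintf("'%s' must not be NA", nm))
      return(NA_real_)
    }
    as.numeric(x)
  }
  p <- list(
    kH = num1(kH, "kH"), kH2O = num1(kH2O, "kH2O"), kOH = num1(kOH, "kOH"),
    kcat = num1(kcat, "kcat"), Ka = num1(Ka, "Ka", allow_na = TRUE),
    KW = num1(KW, "KW")
  )
  for (nm in c("kH", "kH2O", "kOH", "kcat"))
    if (p[[nm]] < 0) stop_validation(sprintf("'%s' must be >= 0", nm))
  if (p$KW <= 0) stop_validation("'KW' must be > 0")
  if (p$kcat > 0 && (is.na(p$Ka) || p$Ka <= 0))
    stop_validation("'Ka' must be > 0 whenever 'kcat' > 0")
  if (!is.na(p$Ka) && p$Ka < 0) stop_validation("'Ka' must be >= 0")
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("pH-rate law parameters:\n")
  cat(sprintf("  kH   = %.4g M^-1 s^-1\n", x$kH))
  cat(sprintf("  kH2O = %.4g s^-1\n", x$kH2O))
  cat(sprintf("  kOH  = %.4g M^-1 s^-1\n", x$kOH))
  cat(sprintf("  kcat = %.4g M^-1 s^-1\n", x$kcat))
  cat(sprintf("  Ka   = %s M (Ka1 = Ka2)\n",
              if (is.na(x$Ka)) "n.a." else sprintf("%.4g", x$Ka)))
  cat(sprintf("  KW   = %.4g M^2\n", x$KW))
  invisible(x)
}

#' Reference parameter sets for the arylmercury-catalyzed system
#'
#' Literature estimates of the rate and kinetic acidity constants for the
#' cleavage of adenylyl-3',5'-(2',3'-O-methyleneadenosine) and its
#' 2',5'-isomer at 90 degrees C, I(NaNO3) = 0.1 M, 30 mM buffer, determined
#' without catalyst and in the presence of 1 mM of a water-soluble
#' arylmercury complex.  These sets serve as ground truth for the
#' synthetic-data generator and as sanity anchors for the fitting routines.
#'
#' @param catalyst Logical; if `TRUE`, return the parameter set estimated in
#'   the presence of the arylmercury catalyst (includes `kcat` and `Ka`),
#'   otherwise the background (no-catalyst) set.
#' @return A [rate_params] object.
#' @examples
#' ref_rate_params()
#' ref_rate_params(catalyst = TRUE)
#' @export
ref_rate_params <- function(catalyst = FALSE) {
  if (isTRUE(catalyst)) {
    rate_params(kH = 3e-3, kH2O = 1e-7, kOH = 0.07, kcat = 1.6e-3, Ka = 3e-6)
  } else {
    rate_params(kH = 2.4e-3, kH2O = 1.3e-7, kOH = 0.10)
  }
}

#' Experimental conditions
#'
#' Bundle of the solution conditions under which an observed rate constant
#' applies.  Only `pH` and `cat_conc` enter the rate law; temperature,
#' ionic strength and buffer concentration are carried as metadata (buffer
#' catalysis is assumed absent).
#'
#' @param pH Solution pH (unitless, 0-14).
#' @param cat_conc Catalyst concentration (M), >= 0.
#' @param temperature_C Temperature in degrees C (metadata; default 90).
#' @param ionic_strength_M Ionic strength in M (metadata; default 0.1).
#' @param buffer_mM Buffer concentration in mM (metadata; default 30).
#' @return An object of class `conditions`.
#' @export
conditions <- function(pH, cat_conc = 0, temperature_C = 90,
                       ionic_strength_M = 0.1, buffer_mM = 30) {
  if (!is.numeric(pH) || any(is.na(pH)) || any(pH < 0) || any(pH > 14))
    stop_validation("'pH' must lie in [0, 14]")
  if (!is.numeric(cat_conc) || any(is.na(cat_conc)) || any(cat_conc < 0))
    stop_validation("'cat_conc' must be >= 0")
  structure(list(pH = as.numeric(pH), cat_conc = as.numeric(cat_conc),
                 temperature_C = temperature_C,
                 ionic_strength_M = ionic_strength_M,
                 buffer_mM = buffer_mM),
            class = "conditions")
}

#' Serialize rate-law parameters to JSON
#'
#' Writes (or returns) a JSON object with keys `kH`, `kH2O`, `kOH`, `kcat`,
#' `Ka`, `KW` in SI units (M^-1 s^-1, s^-1, M, M^2).
#'
#' @param params A [rate_params] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly, when written to a file).
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "rate_params"))
  txt <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                          na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Deserialize rate-law parameters from JSON
#'
#' @param x A JSON string or a path to a JSON file produced by
#'   [params_to_json()] (extra keys are ignored).
#' @return A [rate_params] object.
#' @export
params_from_json <- function(x) {
  obj <- if (file.exists(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else jsonlite::fromJSON(x)
  get0n <- function(nm, default) {
    v <- obj[[nm]]
    if (is.null(v)) default else as.numeric(v)
  }
  rate_params(kH = get0n("kH", 0), kH2O = get0n("kH2O", 0),
              kOH = get0n("kOH", 0), kcat = get0n("kcat", 0),
              Ka = get0n("Ka", NA_real_), KW = get0n("KW", 6.2e-13))
}
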