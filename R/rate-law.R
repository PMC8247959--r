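#' Hydronium-ion concentration from pH
#'
#' Concentration-scale convention: \[H+\] = 10^(-pH).  Activity corrections
#' are not applied; the ionic product of water used alongside this
#' convention is likewise on the concentration scale.
#'
#' @param pH Numeric vector of pH values in \[0, 14\].
#' @return Hydronium concentration(s) in M; strictly decreasing in pH.
#' @examples
#' hydronium_conc(7)   # 1e-7
#' @export
hydronium_conc <- function(pH) {
  if (!is.numeric(pH) || any(is.na(pH)) || any(pH < 0) || any(pH > 14))
    stop_validation("'pH' must be numeric in [0, 14]")
  10^(-as.numeric(pH))
}

#' Speciation fraction of the reactive (doubly deprotonated) form
#'
#' Fraction of the catalyst-substrate ensemble present in the doubly
#' deprotonated form of a diprotic equilibrium with shared acidity constant
#' Ka (Ka1 = Ka2):
#' \deqn{f([H^+]) = Ka^2 / ([H^+]^2 + Ka [H^+] + Ka^2)}
#' The fraction is bounded in (0, 1), decreases monotonically with
#' \[H+\], tends to 1 as \[H+\] tends to 0 and equals exactly 1/3 at
#' \[H+\] = Ka.
#'
#' @param params A [rate_params] object, or a single numeric Ka value (M).
#' @param hconc Hydronium concentration(s) in M; must be > 0.
#' @return Unitless fraction(s) in (0, 1).
#' @examples
#' speciation_fraction(3e-6, hconc = 3e-6)  # exactly 1/3
#' @export
speciation_fraction <- function(params, hconc) {
  Ka <- if (inherits(params, "rate_params")) params$Ka else params
  if (!is.numeric(Ka) || length(Ka) != 1L || is.na(Ka) || Ka <= 0)
    stop_validation("'Ka' must be a single positive number")
  if (!is.numeric(hconc) || any(is.na(hconc)) || any(hconc <= 0))
    stop_validation("'hconc' must be > 0")
  Ka^2 / (hconc^2 + Ka * hconc + Ka^2)
}

#' Observed cleavage rate constant predicted by the pH-rate law
#'
#' Evaluates the four-term rate law for the observed first-order cleavage
#' rate constant of the dinucleoside monophosphate pool:
#' \deqn{k_{cl} = k_H [H^+] + k_{H_2O}
#'   + k_{cat} [cat] \frac{K_a^2}{[H^+]^2 + K_a [H^+] + K_a^2}
#'   + k_{OH} \frac{K_W}{[H^+]}}
#' With `cat_conc = 0` the law reduces exactly to the three-term background
#' law and is invariant to `kcat` and `Ka`.
#'
#' @param params A [rate_params] object.
#' @param pH pH value(s), or a [conditions] object (in which case
#'   `cat_conc` is taken from it).
#' @param cat_conc Catalyst concentration(s) in M (recycled against `pH`).
#' @return Predicted rate constant(s) in s^-1.
#' @examples
#' cleavage_rate(ref_rate_params(), pH = 7)
#' @export
cleavage_rate <- function(params, pH, cat_conc = 0) {
  stopifnot(inherits(params, "rate_params"))
  if (inherits(pH, "conditions")) {
    cat_conc <- pH$cat_conc
    pH <- pH$pH
  }
  if (any(cat_conc < 0)) stop_validation("'cat_conc' must be >= 0")
  terms <- rate_terms(params, pH, cat_conc)
  terms$kH + terms$kH2O + terms$kcat + terms$kOH
}

#' Term-by-term decomposition of the pH-rate law
#'
#' @inheritParams cleavage_rate
#' @return A data frame with one row per pH and columns `kH`, `kH2O`,
#'   `kcat`, `kOH` holding the four additive contributions (s^-1); their
#'   row sums equal [cleavage_rate()].
#' @export
rate_terms <- function(params, pH, cat_conc = 0) {
  stopifnot(inherits(params, "rate_params"))
  h <- hydronium_conc(pH)
  n <- max(length(h), length(cat_conc))
  h <- rep_len(h, n)
  cc <- rep_len(as.numeric(cat_conc), n)
  cat_term <- if (params$kcat > 0) {
    params$kcat * cc * speciation_fraction(params, h)
  } else {
    rep(0, n)
  }
  data.frame(kH = params$kH * h,
             kH2O = rep(params$kH2O, n),
             kcat = cat_term,
             kOH = params$kOH * params$KW / h)
}

#' Fold acceleration of cleavage by the catalyst
#'
#' Ratio of the rate predicted by the full law (with catalyst present) to
#' the rate predicted by a background-only law at the same pH.  Equals 1 at
#' every pH when `kcat = 0`, and is >= 1 and nondecreasing in `cat_conc`
#' when `kcat > 0`.
#'
#' @param params_bg [rate_params] describing the background (no-catalyst)
#'   reaction; its catalytic term is ignored (evaluated at zero catalyst).
#' @param params_cat [rate_params] describing the reaction in the presence
#'   of catalyst.  Defaults to `params_bg`.
#' @param pH pH value(s).
#' @param cat_conc Catalyst concentration (M); must be > 0.
#' @return Unitless fold acceleration(s).
#' @examples
#' acceleration_ratio(ref_rate_params(), ref_rate_params(TRUE),
#'                    pH = 7, cat_conc = 1e-3)
#' @export
acceleration_ratio <- function(params_bg, params_cat = params_bg, pH,
                               cat_conc) {
  stopifnot(inherits(params_bg, "rate_params"),
            inherits(params_cat, "rate_params"))
  if (any(cat_conc <= 0)) stop_validation("'cat_conc' must be > 0")
  denom <- cleavage_rate(params_bg, pH, cat_conc = 0)
  if (any(denom <= 0))
    stop_data("background rate is zero: acceleration ratio undefined")
  cleavage_rate(params_cat, pH, cat_conc) / denom
}

#' Local slope of the pH-rate profile on log-log axes
#'
#' Central-difference slope of log10(k_cl) with respect to pH.  For a pure
#' hydroxide term the slope is +1, for a pure hydronium term -1, and for
#' the isolated catalytic term in the \[H+\] >> Ka regime it approaches +2
#' (apparent second-order dependence on \[OH-\]).  For the full law with
#' nonnegative constants the slope is bounded in \[-1, +2\].
#'
#' @param params A [rate_params] object.
#' @param pH pH value(s) at which to evaluate the slope.
#' @param cat_conc Catalyst concentration (M).
#' @param dpH Half-width of the central difference (default 0.01).
#' @return Unitless slope(s) d log10(k) / d pH.
#' @export
loglog_slope <- function(params, pH, cat_conc = 0, dpH = 0.01) {
  if (!is.numeric(dpH) || dpH <= 0)
    stop_validation("'dpH' must be a positive step")
  up <- log10(cleavage_rate(params, pH + dpH, cat_conc))
  dn <- log10(cleavage_rate(params, pH - dpH, cat_conc))
  (up - dn) / (2 * dpH)
}
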