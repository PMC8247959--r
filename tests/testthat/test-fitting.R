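truth_bg <- ref_rate_params()
truth_cat <- ref_rate_params(catalyst = TRUE)

test_that("noise-free profiles are refitted to the generating parameters", {
  design <- experiment_design()
  f_bg <- fit_ph_profile(gen_ph_profile(truth_bg, design, 0))
  expect_true(f_bg$converged)
  expect_identical(sort(f_bg$free), sort(c("kH", "kH2O", "kOH")))
  for (nm in f_bg$free)
    expect_lt(abs(f_bg$estimates[[nm]] - truth_bg[[nm]]) / truth_bg[[nm]],
              1e-4)
  f_cat <- fit_ph_profile(gen_ph_profile(truth_cat, design, 1e-3))
  expect_true(f_cat$converged)
  for (nm in f_cat$free)
    expect_lt(abs(f_cat$estimates[[nm]] - truth_cat[[nm]]) /
                truth_cat[[nm]], 1e-4)
  # noise-free global sanity: optimum no worse than the truth
  expect_lte(f_cat$objective,
             profile_objective(truth_cat,
                               gen_ph_profile(truth_cat, design, 1e-3)) +
               1e-12)
})

test_that("optimum beats a coarse grid search over (kcat, Ka)", {
  prof <- gen_ph_profile(truth_cat, experiment_design(), 1e-3)
  fit <- fit_ph_profile(prof)
  grid <- expand.grid(kcat = 1.6e-3 * c(0.25, 0.5, 1, 2, 4),
                      Ka = 3e-6 * c(0.25, 0.5, 1, 2, 4))
  obj <- mapply(function(kc, ka) {
    profile_objective(rate_params(kH = truth_cat$kH,
                                  kH2O = truth_cat$kH2O,
                                  kOH = truth_cat$kOH, kcat = kc, Ka = ka),
                      prof)
  }, grid$kcat, grid$Ka)
  expect_lte(fit$objective, min(obj) + 1e-12)
})

test_that("fits are invariant to point order and unit-consistent rescaling", {
  prof <- gen_ph_profile(truth_cat, experiment_design(), 1e-3,
                         noise_model("multiplicative-lognormal", 0.1,
                                     seed = 31))
  fit <- fit_ph_profile(prof)
  idx <- rev(seq_len(nrow(prof)))
  shuffled <- ph_profile(prof$pH[idx], prof$k_obs[idx], prof$se[idx],
                         cat_conc = 1e-3)
  fit_sh <- fit_ph_profile(shuffled)
  expect_equal(fit_sh$estimates, fit$estimates, tolerance = 1e-8)
  # rescaling k_obs (and se) by a constant rescales the rate constants and
  # leaves Ka untouched
  sc <- 60
  scaled <- ph_profile(prof$pH, prof$k_obs * sc, prof$se * sc,
                       cat_conc = 1e-3)
  fit_sc <- fit_ph_profile(scaled)
  for (nm in c("kH", "kH2O", "kOH", "kcat"))
    expect_equal(fit_sc$estimates[[nm]], sc * fit$estimates[[nm]],
                 tolerance = 1e-6)
  expect_equal(fit_sc$estimates$Ka, fit$estimates$Ka, tolerance = 1e-6)
})

test_that("structural identifiability is enforced", {
  prof_bg <- gen_ph_profile(truth_bg, experiment_design(), 0)
  expect_error(fit_ph_profile(prof_bg, start = list(Ka = 1e-6)),
               class = "phratefit_validation_error")
  tiny <- ph_profile(c(3, 5, 7, 8.5),
                     cleavage_rate(truth_cat, c(3, 5, 7, 8.5), 1e-3),
                     cat_conc = 1e-3)
  expect_error(fit_ph_profile(tiny),
               class = "phratefit_validation_error")  # n < p + 2
  expect_error(fit_ph_profile(prof_bg, fix = list(bogus = 1)),
               class = "phratefit_validation_error")
})

test_that("noisy replicates recover parameters without systematic bias and
           with near-nominal interval coverage", {
  set.seed(808)
  seeds <- sample.int(1e6, 200)
  design <- experiment_design()
  truth <- c(kH = 2.4e-3, kH2O = 1.3e-7, kOH = 0.10, kcat = 1.6e-3,
             Ka = 3e-6)
  n_rep <- 100
  est <- se <- matrix(NA_real_, n_rep, 5,
                      dimnames = list(NULL, names(truth)))
  for (i in seq_len(n_rep)) {
    noise_b <- noise_model("multiplicative-lognormal", 0.1, seeds[i])
    noise_c <- noise_model("multiplicative-lognormal", 0.1,
                           seeds[n_rep + i])
    fb <- fit_ph_profile(gen_ph_profile(truth_bg, design, 0, noise_b))
    fc <- fit_ph_profile(gen_ph_profile(truth_cat, design, 1e-3, noise_c))
    est[i, ] <- c(fb$estimates$kH, fb$estimates$kH2O, fb$estimates$kOH,
                  fc$estimates$kcat, fc$estimates$Ka)
    se[i, ] <- c(fb$se[c("kH", "kH2O", "kOH")],
                 fc$se[c("kcat", "Ka")])
  }
  for (nm in names(truth)) {
    bias <- stats::median((est[, nm] - truth[nm]) / truth[nm])
    expect_lt(abs(bias), 0.05)
  }
  covered <- abs(sweep(est, 2, truth)) <= se
  coverage <- mean(covered)  # pooled over the five parameters
  expect_gte(coverage, 0.55)
  expect_lte(coverage, 0.80)
})

test_that("concentration-series fits recover exact lines and the closed
           form weighted slope", {
  a <- 5e-7
  b <- 1.5e-3
  cc <- seq(0, 7e-3, by = 1e-3)
  ser <- conc_series(cc, a + b * cc, se = 0.1 * (a + b * cc), pH = 7)
  fit <- fit_conc_series(ser)
  expect_equal(fit$intercept, a, tolerance = 1e-10)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  # noisy series: agree with the weighted normal equations solved by hand
  noisy <- gen_conc_series(truth_cat, experiment_design(), 7,
                           noise_model("multiplicative-lognormal", 0.1,
                                       seed = 99))
  fit_n <- fit_conc_series(noisy)
  oracle <- wls_line(noisy$cat_conc, noisy$k_obs, 1 / noisy$se^2)
  expect_equal(fit_n$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit_n$intercept, unname(oracle["intercept"]),
               tolerance = 1e-10)
  expect_error(fit_conc_series(conc_series(c(0, 1e-3), c(1e-7, 2e-7))),
               class = "phratefit_validation_error")
})

test_that("the apparent slope equals kcat times the speciation fraction", {
  ser <- gen_conc_series(truth_cat, experiment_design(), 7)
  fit <- fit_conc_series(ser, speciation_correction = TRUE, Ka = 3e-6)
  f7 <- speciation_fraction(3e-6, 1e-7)
  expect_equal(fit$slope, truth_cat$kcat * f7, tolerance = 1e-8)
  expect_equal(fit$kcat_intrinsic, truth_cat$kcat, tolerance = 1e-8)
  expect_error(fit_conc_series(ser, speciation_correction = TRUE),
               class = "phratefit_validation_error")
})

test_that("fit reports tabulate scaled units, mark n.a. and round-trip", {
  design <- experiment_design()
  f_cat <- fit_ph_profile(gen_ph_profile(truth_cat, design, 1e-3))
  rep_cat <- profile_report(f_cat)
  tb <- rep_cat$param_table
  got <- signif(tb$value_scaled, 2)
  names(got) <- tb$parameter
  expect_equal(got[c("kH", "kH2O", "kOH", "kcat", "Ka")],
               c(kH = 3, kH2O = 1, kOH = 0.07, kcat = 1.6, Ka = 3))
  expect_equal(params_from_report(rep_cat), f_cat$estimates)
  # catalyst-free fit marks the catalytic entries n.a.
  f_bg <- fit_ph_profile(gen_ph_profile(truth_bg, design, 0))
  rep_bg <- profile_report(f_bg)
  tb_bg <- rep_bg$param_table
  expect_identical(tb_bg$display[tb_bg$parameter %in% c("kcat", "Ka")],
                   c("n.a.", "n.a."))
  expect_equal(signif(tb_bg$value_scaled[1:3], 2), c(2.4, 1.3, 0.10))
  txt <- format(rep_bg)
  expect_true(any(grepl("2.4", txt, fixed = TRUE)))
  expect_true(any(grepl("n.a.", txt, fixed = TRUE)))
})
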