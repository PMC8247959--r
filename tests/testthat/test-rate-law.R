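test_that("hydronium concentration follows the 10^(-pH) convention", {
  expect_equal(hydronium_conc(7), 1e-7)
  expect_equal(hydronium_conc(0), 1)
  expect_equal(hydronium_conc(5.3), 10^-5.3)
  grid <- seq(0, 14, by = 0.5)
  expect_true(all(diff(hydronium_conc(grid)) < 0))
  expect_error(hydronium_conc(-0.1), class = "phratefit_validation_error")
  expect_error(hydronium_conc(14.5), class = "phratefit_validation_error")
})

test_that("speciation fraction has the symmetric diprotic form", {
  expect_equal(speciation_fraction(3e-6, 3e-6), 1 / 3)
  # hand arithmetic: Ka^2 = 9e-12, h^2 = 1e-12, Ka*h = 3e-12
  expect_equal(speciation_fraction(3e-6, 1e-6), 9 / 13)
  expect_equal(speciation_fraction(3e-6, 1e-15), 1, tolerance = 1e-8)
  expect_lt(speciation_fraction(3e-6, 1), 1e-10)
  expect_error(speciation_fraction(3e-6, 0),
               class = "phratefit_validation_error")
  expect_error(speciation_fraction(3e-6, -1e-7),
               class = "phratefit_validation_error")
})

test_that("speciation fraction is bounded and monotone for random inputs", {
  set.seed(101)
  for (i in 1:20) {
    Ka <- 10^stats::runif(1, -9, -3)
    h <- sort(10^stats::runif(25, -12, 0))
    f <- speciation_fraction(Ka, h)
    expect_true(all(f > 0 & f < 1))
    expect_true(all(diff(f) < 0))
  }
})

test_that("the rate law reduces to its individual terms", {
  expect_equal(cleavage_rate(rate_params(kH2O = 1e-7), pH = 4), 1e-7)
  expect_equal(cleavage_rate(rate_params(kH2O = 1e-7), pH = 8), 1e-7)
  # hand sum at pH 7, no catalyst: 2.4e-3*1e-7 + 1.3e-7 + 0.10*6.2e-13/1e-7
  p_bg <- rate_params(kH = 2.4e-3, kH2O = 1.3e-7, kOH = 0.10)
  expect_equal(cleavage_rate(p_bg, 7), 2.4e-10 + 1.3e-7 + 6.2e-7)
})

test_that("the law is additive and background-reducible", {
  p <- rate_params(kH = 3e-3, kH2O = 1e-7, kOH = 0.07, kcat = 1.6e-3,
                   Ka = 3e-6)
  pH <- seq(3, 8.5, by = 0.25)
  terms <- rate_terms(p, pH, cat_conc = 1e-3)
  expect_equal(rowSums(terms), cleavage_rate(p, pH, 1e-3))
  # zeroing one constant removes exactly that term
  p0 <- rate_params(kH = 0, kH2O = 1e-7, kOH = 0.07, kcat = 1.6e-3,
                    Ka = 3e-6)
  expect_equal(cleavage_rate(p, pH, 1e-3) - cleavage_rate(p0, pH, 1e-3),
               terms$kH)
  # with no catalyst the law is invariant to kcat and Ka
  p_alt <- rate_params(kH = 3e-3, kH2O = 1e-7, kOH = 0.07, kcat = 9e-2,
                       Ka = 5e-8)
  expect_equal(cleavage_rate(p, pH, 0), cleavage_rate(p_alt, pH, 0))
})

test_that("acceleration ratio matches the catalyzed/background fold", {
  bg <- ref_rate_params()
  ct <- ref_rate_params(catalyst = TRUE)
  expect_equal(acceleration_ratio(bg, bg, pH = seq(3, 8, 1),
                                  cat_conc = 1e-3),
               rep(1, 6))  # kcat = 0 implies no acceleration
  r7 <- acceleration_ratio(bg, ct, pH = 7, cat_conc = 1e-3)
  expect_equal(r7, 3, tolerance = 0.15)
  expect_lte(max(acceleration_ratio(bg, ct, seq(3, 8.5, by = 0.01), 1e-3)),
             8)
  # monotone nondecreasing in catalyst concentration at fixed pH
  cc <- seq(1e-4, 7e-3, length.out = 30)
  expect_true(all(diff(acceleration_ratio(bg, ct, 6.5, cc)) >= 0))
  expect_error(acceleration_ratio(rate_params(), ct, 7, 1e-3),
               class = "phratefit_data_error")
  expect_error(acceleration_ratio(bg, ct, 7, 0),
               class = "phratefit_validation_error")
})

test_that("log-log slopes recover the reaction orders of each term", {
  expect_equal(loglog_slope(rate_params(kOH = 0.1), pH = c(4, 6, 8)),
               rep(1, 3), tolerance = 1e-6)
  expect_equal(loglog_slope(rate_params(kH = 1e-3), pH = c(4, 6, 8)),
               rep(-1, 3), tolerance = 1e-6)
  # isolated catalytic term in the [H+] >> Ka regime: second order in [OH-]
  expect_equal(loglog_slope(rate_params(kcat = 1e-3, Ka = 3e-6), pH = 4,
                            cat_conc = 1e-3, dpH = 1e-3),
               2, tolerance = 0.05)
})

test_that("slope of the full law stays within [-1, +2]", {
  set.seed(77)
  for (i in 1:15) {
    p <- rate_params(kH = 10^stats::runif(1, -5, -2),
                     kH2O = 10^stats::runif(1, -8, -6),
                     kOH = 10^stats::runif(1, -2, 0),
                     kcat = 10^stats::runif(1, -4, -2),
                     Ka = 10^stats::runif(1, -8, -4))
    s <- loglog_slope(p, seq(1, 13, by = 0.25), cat_conc = 1e-3)
    expect_true(all(s >= -1 - 1e-6 & s <= 2 + 1e-6))
  }
})

test_that("parameter containers validate their invariants", {
  expect_error(rate_params(kH = -1), class = "phratefit_validation_error")
  expect_error(rate_params(KW = 0), class = "phratefit_validation_error")
  expect_error(rate_params(kcat = 1e-3),
               class = "phratefit_validation_error")  # kcat > 0 needs Ka
  expect_error(conditions(pH = 15), class = "phratefit_validation_error")
  expect_error(conditions(pH = 7, cat_conc = -1),
               class = "phratefit_validation_error")
  cond <- conditions(pH = 5.5, cat_conc = 2e-3)
  p <- ref_rate_params(TRUE)
  expect_equal(cleavage_rate(p, cond), cleavage_rate(p, 5.5, 2e-3))
})

test_that("rate-law parameters round-trip through JSON", {
  p <- ref_rate_params(TRUE)
  expect_equal(params_from_json(params_to_json(p)), p)
  bg <- ref_rate_params()
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(bg, path)
  expect_equal(params_from_json(path), bg)
})
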