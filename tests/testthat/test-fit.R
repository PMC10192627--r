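test_that("chi-square error percentage matches hand computation", {
  # zero residuals
  expect_equal(chi2_error_percent(c(5, 10, 20), c(5, 10, 20), 2), 0)
  # worked example: df = 2, qchisq(0.95, 2) = 5.991, mean = 20, SSR = 3
  expect_equal(chi2_error_percent(c(10, 20, 30), c(11, 19, 31), 1),
               100 / 20 * sqrt(3 / qchisq(0.95, 2)), tolerance = 1e-12)
  expect_equal(round(chi2_error_percent(c(10, 20, 30), c(11, 19, 31), 1), 2), 3.54)
  # invariant under common rescaling
  expect_equal(chi2_error_percent(2 * c(10, 20, 30), 2 * c(11, 19, 31), 1),
               chi2_error_percent(c(10, 20, 30), c(11, 19, 31), 1))
  # degrees-of-freedom and zero-mean guards
  expect_error(chi2_error_percent(c(1, 2), c(1, 2), 2), class = "mineralkin_error")
  expect_error(chi2_error_percent(c(0, 0), c(0, 0), 1), class = "mineralkin_error")
  expect_error(chi2_error_percent(c(1, 2), c(1, 2, 3), 1), class = "mineralkin_error")
})

test_that("noise-free curves are fitted back to their generating parameters", {
  # SFO with a plateau at 40% of applied
  curve <- simulate_curve(kin_params("SFO", k1 = 0.02, m_max = 40),
                          schedule = c(0, 1, 3, 7, 14, 21, 28, 42, 60, 80, 100, 120),
                          noise_sd = 0, seed = 1)
  f <- fit_kinetics(curve, "SFO")
  expect_lt(abs(f$params$k1 - 0.02) / 0.02, 1e-3)
  expect_lt(abs(f$params$m_max - 40), 0.05)
  expect_lt(f$chi2_error_pct, 0.01)
  expect_true(f$converged)

  # HS: breakpoint recovered within half a day
  curve_hs <- simulate_curve(kin_params("HS", k1 = 0.03, k2 = 5e-4, tb = 12),
                             noise_sd = 0, seed = 1)
  f_hs <- fit_kinetics(curve_hs, "HS")
  expect_lt(abs(f_hs$params$tb - 12), 0.5)
  expect_lt(f_hs$chi2_error_pct, 0.01)

  # FOMC
  curve_f <- simulate_curve(kin_params("FOMC", alpha = 2, beta = 64.4),
                            noise_sd = 0, seed = 1)
  f_f <- fit_kinetics(curve_f, "FOMC")
  expect_lt(abs(f_f$params$alpha - 2) / 2, 1e-3)
  expect_lt(f_f$chi2_error_pct, 0.01)
})

test_that("underdetermined fits and out-of-range observations error", {
  short <- tiny_curve_df(times = c(0, 7, 14), values = c(0, 10, 18))
  expect_error(fit_kinetics(short, "HS"), class = "mineralkin_fit_error")
  bad <- tiny_curve_df(times = c(0, 7, 14, 21, 28), values = c(0, 10, 50, 90, 130))
  expect_error(fit_kinetics(bad, "SFO"), class = "mineralkin_error")
})

test_that("an all-zero curve is flagged, not silently accepted", {
  flat <- tiny_curve_df(times = c(0, 7, 14, 28, 60, 120), values = rep(0, 6))
  f <- fit_kinetics(flat, "SFO")
  expect_false(f$converged)
  expect_true(f$bound_active)
  expect_true(is.na(f$chi2_error_pct))
})

test_that("model selection follows the chi-square error with tie-breaks and flags", {
  # smaller error wins
  sel <- select_model(list(stub_fit("SFO", 6.2, 2), stub_fit("FOMC", 3.1, 3)))
  expect_identical(sel$model, "FOMC")
  expect_false(sel$poor_fit)
  # within 0.1 points: fewer parameters win
  sel2 <- select_model(list(stub_fit("SFO", 3.10, 2), stub_fit("HS", 3.15, 4)))
  expect_identical(sel2$model, "SFO")
  # both above the 15% acceptability rule: winner carries the poor-fit flag
  sel3 <- select_model(list(stub_fit("SFO", 22, 2), stub_fit("FOMC", 18, 3)))
  expect_identical(sel3$model, "FOMC")
  expect_true(sel3$poor_fit)
  # non-converged fits are never selected
  expect_error(select_model(list(stub_fit("SFO", 1, 2, converged = FALSE))),
               class = "mineralkin_fit_error")
  expect_error(select_model(list()), class = "mineralkin_error")
})

test_that("fitting is bit-reproducible given the seed", {
  curve <- simulate_curve(kin_params("HS", k1 = 0.03, k2 = 5e-4, tb = 12),
                          noise_sd = 1.5, seed = 11)
  f1 <- fit_kinetics(curve, "HS", seed = 99)
  f2 <- fit_kinetics(curve, "HS", seed = 99)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$ssr, f2$ssr)
})

test_that("the hockey-stick fit never does worse than the SFO it nests", {
  for (s in c(3, 17, 42)) {
    curve <- simulate_curve(kin_params("SFO", k1 = 0.015, m_max = 60),
                            noise_sd = 1.5, seed = s)
    f_sfo <- fit_kinetics(curve, "SFO", seed = s)
    f_hs <- fit_kinetics(curve, "HS", seed = s)
    expect_lte(f_hs$ssr, f_sfo$ssr * (1 + 1e-6))
  }
})

test_that("fit_study drives the batch and records per-curve failures", {
  expect_identical(nrow(fit_study(tibble::tibble(soil = character(),
                                                 treatment = character(),
                                                 replicate = integer(),
                                                 time_d = double(),
                                                 cum_pct = double()))), 0L)
  truth <- published_truth(soils = "CR", treatments = c("B", "C"))
  study <- simulate_study(study_config(truth = truth, seed = 4))
  fits <- fit_study(study, seed = 4)
  expect_identical(nrow(fits), 2L)
  expect_true(all(c("model", "dt50", "chi2_error_pct", "fit") %in% names(fits)))
  # a curve too short for the requested model is recorded, batch continues
  broken <- dplyr::bind_rows(study,
                             tiny_curve_df(soil = "ZZ", treatment = "A"))
  fits2 <- fit_study(broken, models = "HS", seed = 4)
  expect_identical(nrow(fits2), 3L)
  expect_true(any(!is.na(fits2$error)))
  expect_true(all(is.na(fits2$error[fits2$soil != "ZZ"])))
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  curve <- simulate_curve(kin_params("FOMC", alpha = 2, beta = 64.4),
                          noise_sd = 1, seed = 2)
  f <- fit_kinetics(curve, "FOMC")
  td <- tidy(f)
  expect_setequal(td$term, c("alpha", "beta", "m_max"))
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("dt50", "chi2_error_pct", "converged") %in% names(gl)))
  au <- augment(f)
  expect_identical(nrow(au), length(unique(curve$time_d)))
  expect_equal(au$observed - au$fitted, au$residual)
})
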