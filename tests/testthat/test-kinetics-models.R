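test_that("SFO curve matches closed-form landmarks", {
  expect_equal(sfo_curve(0, k1 = 0.02), 0)
  # half of the amplitude is mineralized at t = ln2/k1
  expect_equal(sfo_curve(log(2) / 0.02, k1 = 0.02), 50)
  # direct evaluation of 100 (1 - e^{-k1 t})
  expect_equal(sfo_curve(120, k1 = 1.2e-3), 100 * (1 - exp(-1.2e-3 * 120)),
               tolerance = 1e-12)
  expect_equal(round(sfo_curve(120, k1 = 1.2e-3), 2), 13.41)
})

test_that("FOMC curve matches closed-form landmarks", {
  expect_equal(fomc_curve(0, alpha = 1.7, beta = 12), 0)
  # alpha = 1: half mineralized exactly at t = beta
  expect_equal(fomc_curve(64.4, alpha = 1, beta = 64.4), 50)
  # the closed-form DT50 beta (2^{1/alpha} - 1) inverts the curve
  t50 <- 64.4 * (2^(1 / 2) - 1)
  expect_equal(fomc_curve(t50, alpha = 2, beta = 64.4), 50, tolerance = 1e-12)
})

test_that("hockey-stick curve is continuous, biphasic and nests SFO", {
  k1 <- 0.014; k2 <- 7.2e-4; tb <- 12.3
  # first phase identical to SFO
  tt <- seq(0, tb, length.out = 25)
  expect_equal(hs_curve(tt, k1, k2, tb), sfo_curve(tt, k1))
  # continuity at the breakpoint
  expect_equal(hs_curve(tb - 1e-10, k1, k2, tb), hs_curve(tb + 1e-10, k1, k2, tb),
               tolerance = 1e-7)
  # second-phase value from the exponent k1 tb + k2 (t - tb)
  expect_equal(hs_curve(120, k1, k2, tb),
               100 * (1 - exp(-(k1 * tb + k2 * (120 - tb)))), tolerance = 1e-12)
  expect_equal(round(hs_curve(120, k1, k2, tb), 2), 22.10)
  # k1 = k2 collapses to plain first order at machine precision
  t_all <- c(0, 0.5, 3, 11.9, 12, 30, 120, 500)
  expect_equal(hs_curve(t_all, 0.01, 0.01, 12), sfo_curve(t_all, 0.01))
})

test_that("negative times and invalid parameters are rejected", {
  expect_error(sfo_curve(-1, k1 = 0.02), class = "mineralkin_error")
  expect_error(hs_curve(c(3, -2), 0.01, 0.001, 5), class = "mineralkin_error")
  expect_error(kin_params("SFO", k1 = -0.1), class = "mineralkin_error")
  expect_error(kin_params("FOMC", alpha = 1), class = "mineralkin_error") # no beta
  expect_error(kin_params("HS", k1 = 0.1, k2 = 0.01, tb = 5, m_max = 120),
               class = "mineralkin_error")
  expect_error(kin_params("DFOP", k1 = 0.1), class = "mineralkin_error")
})

test_that("all models start at zero and increase monotonically", {
  for (model in c("SFO", "FOMC", "HS")) {
    for (i in 1:25) {
      p <- random_params(model, rng_seed = 1000 * i + match(model, c("SFO", "FOMC", "HS")))
      tt <- sort(withr::with_seed(i, runif(40, 0, 500)))
      m <- kin_curve(c(0, tt), p)
      expect_equal(m[1], 0)
      expect_true(all(diff(m) >= -1e-12),
                  label = sprintf("%s monotone (draw %d)", model, i))
      expect_true(all(m < p$m_max + 1e-9))
    }
  }
})

test_that("FOMC approaches SFO in the large-beta limit", {
  # deviation scales as 100 e^{-kt} k t^2 / (2 beta), < 1e-3 here
  k <- 0.05; beta <- 1e6
  tt <- seq(0, 120, by = 0.5)
  expect_lt(max(abs(fomc_curve(tt, alpha = k * beta, beta = beta) -
                    sfo_curve(tt, k1 = k))), 1e-3)
})
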