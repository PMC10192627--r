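# Shared fixtures: random parameter draws and a tiny handmade curve.

random_params <- function(model, rng_seed) {
  withr::with_seed(rng_seed, {
    switch(model,
      SFO  = kin_params("SFO", k1 = 10^runif(1, -4, -0.5)),
      FOMC = kin_params("FOMC", alpha = 10^runif(1, -1, 1),
                        beta = 10^runif(1, -1, 2.5)),
      HS   = kin_params("HS", k1 = 10^runif(1, -3, -0.5),
                        k2 = 10^runif(1, -5, -1), tb = runif(1, 1, 60))
    )
  })
}

# One curve, one replicate, in the standard long schema.
tiny_curve_df <- function(times = c(0, 7, 14), values = c(0, 10, 18),
                          soil = "S1", treatment = "B", replicate = 1) {
  tibble::tibble(soil = soil, treatment = treatment, replicate = replicate,
                 time_d = times, cum_pct = values)
}

# Minimal stand-in for a fitted object, for exercising select_model().
stub_fit <- function(model, chi2, n_params, converged = TRUE) {
  structure(list(model = model, chi2_error_pct = chi2, n_params = n_params,
                 converged = converged), class = "kin_fit")
}
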