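#' FOCUS chi-square error percentage
#'
#' The minimum relative error level (in % of the mean observation) at which a
#' chi-square test, with degrees of freedom `m - p`, just fails to reject the
#' fit at significance 0.05:
#' \deqn{err\% = \frac{100}{\bar{O}} \sqrt{\frac{\sum_i (O_i - C_i)^2}{\chi^2_{m-p,\,0.95}}}}
#' Values below 15% conventionally denote an acceptable fit of a dissipation
#' curve. The quantile is the exact inverse chi-square CDF ([stats::qchisq()]).
#'
#' @param observed Observed values (% of applied), typically replicate means
#'   per sampling time.
#' @param predicted Model predictions at the same times.
#' @param n_params Number of free model parameters `p`.
#' @param alpha Test significance level; 0.05 is the conventional choice.
#' @return The error percentage (scalar, >= 0). Invariant under a common
#'   rescaling of both vectors.
#' @examples
#' chi2_error_percent(c(10, 20, 30), c(11, 19, 31), n_params = 1)  # 3.54
#' @export
chi2_error_percent <- function(observed, predicted, n_params, alpha = 0.05) {
  m <- length(observed)
  if (length(predicted) != m) {
    abort("'observed' and 'predicted' must have equal length",
          class = "mineralkin_error")
  }
  if (m <= n_params) {
    abort(paste0("chi-square error needs more observations (", m,
                 ") than free parameters (", n_params, ")"),
          class = "mineralkin_error")
  }
  o_bar <- mean(observed)
  if (o_bar <= 0) {
    abort("mean observed value must be > 0 for the chi-square error",
          class = "mineralkin_error")
  }
  ssr <- sum((observed - predicted)^2)
  100 / o_bar * sqrt(ssr / qchisq(1 - alpha, df = m - n_params))
}

# ---- internal: model-specific fitting machinery -----------------------------

model_par_names <- function(model, fix_mmax) {
  base <- switch(model,
    SFO  = "k1",
    FOMC = c("alpha", "beta"),
    HS   = c("k1", "k2", "tb")
  )
  if (fix_mmax) base else c(base, "m_max")
}

# Box bounds on the raw parameter scale. t_max bounds the breakpoint.
model_bounds <- function(model, fix_mmax, t_max) {
  lower <- c(k1 = 1e-8, k2 = 0, tb = 1e-3, alpha = 1e-3, beta = 1e-3, m_max = 1e-6)
  upper <- c(k1 = 10, k2 = 10, tb = t_max, alpha = 50, beta = 1e5, m_max = 100)
  nm <- model_par_names(model, fix_mmax)
  list(lower = lower[nm], upper = upper[nm])
}

# Guarded initial values from the data: k1 from a log-linear regression of the
# early rise, FOMC located at the schedule median, HS breakpoint at the
# schedule midpoint with a 10x slower second phase.
initial_values <- function(model, times, means, fix_mmax) {
  m0 <- max(means, 1e-3)
  plateau <- min(if (fix_mmax) 100 else max(1, 1.05 * m0), 100)
  pos <- times > 0 & means > 0 & means < 0.99 * plateau
  k1_0 <- if (sum(pos) >= 2) {
    y <- -log(pmax(1 - means[pos] / plateau, 1e-8))
    max(unname(coef(lm(y ~ times[pos] - 1))[1]), 1e-6)
  } else if (sum(pos) == 1) {
    max(-log(pmax(1 - means[pos] / plateau, 1e-8)) / times[pos], 1e-6)
  } else {
    1e-4
  }
  start <- switch(model,
    SFO  = c(k1 = k1_0),
    FOMC = c(alpha = 1, beta = max(median(times), 1)),
    HS   = c(k1 = k1_0, k2 = k1_0 / 10,
             tb = max(times[1] + diff(range(times)) / 2, 1))
  )
  if (!fix_mmax) start <- c(start, m_max = plateau)
  start
}

eval_model <- function(model, t, par, m_max_fixed) {
  m_max <- if ("m_max" %in% names(par)) unname(par[["m_max"]]) else m_max_fixed
  switch(model,
    SFO  = m_max * (1 - exp(-par[["k1"]] * t)),
    FOMC = m_max * (1 - (1 + t / par[["beta"]])^(-par[["alpha"]])),
    HS   = {
      expo <- ifelse(t <= par[["tb"]],
                     par[["k1"]] * t,
                     par[["k1"]] * par[["tb"]] + par[["k2"]] * (t - par[["tb"]]))
      m_max * (1 - exp(-expo))
    }
  )
}

par_to_kin_params <- function(model, par, m_max_fixed) {
  m_max <- if ("m_max" %in% names(par)) unname(par[["m_max"]]) else m_max_fixed
  m_max <- min(max(m_max, 1e-6), 100)
  switch(model,
    SFO  = kin_params("SFO", k1 = unname(par[["k1"]]), m_max = m_max),
    FOMC = kin_params("FOMC", alpha = unname(par[["alpha"]]),
                      beta = unname(par[["beta"]]), m_max = m_max),
    HS   = kin_params("HS", k1 = unname(par[["k1"]]), k2 = unname(par[["k2"]]),
                      tb = unname(par[["tb"]]), m_max = m_max)
  )
}

#' Fit one kinetic model to a mineralization curve
#'
#' Bounded least squares on the replicate means per sampling time (the
#' pooled-replicate alternative fits every replicate observation). The
#' optimizer is L-BFGS-B with seeded multi-starts: the data-driven start plus
#' `n_starts - 1` jittered copies (uniform +/-50% per parameter), keeping the
#' best sum of squared residuals. Deterministic given `seed`.
#'
#' @param data A tibble of curve observations with columns `time_d` and
#'   `cum_pct`; an optional `replicate` column is averaged over (default) or
#'   pooled. Extra columns (`soil`, `treatment`, ...) are ignored here.
#' @param model `"SFO"`, `"FOMC"` or `"HS"`.
#' @param fix_mmax If `TRUE`, the amplitude is fixed at 100% of applied;
#'   by default it is a free parameter bounded in (0, 100], since soil
#'   mineralization plateaus far below complete conversion.
#' @param pool_replicates Fit all replicate observations instead of their
#'   per-time means.
#' @param n_starts Number of multi-starts (first is un-jittered).
#' @param seed Integer seed controlling the start jitter.
#' @param basis Basis for the reported DT50/DT90; see [dt_x()].
#' @return A `kin_fit` object; see [tidy()], [glance()], [autoplot()]
#'   methods. Key fields: `params` ([kin_params()]), `dt50`, `dt90`,
#'   `chi2_error_pct`, `ssr`, `residuals`, `extent_observed`, `converged`.
#' @examples
#' curve <- simulate_curve(kin_params("SFO", k1 = 0.02, m_max = 40),
#'                         noise_sd = 0, seed = 1)
#' fit <- fit_kinetics(curve, "SFO")
#' glance(fit)
#' @export
fit_kinetics <- function(data, model = c("SFO", "FOMC", "HS"),
                         fix_mmax = FALSE, pool_replicates = FALSE,
                         n_starts = 10, seed = 1,
                         basis = c("applied", "plateau")) {
  model <- match.arg(toupper(model[1]), c("SFO", "FOMC", "HS"))
  basis <- match.arg(basis)
  stopifnot(is.data.frame(data), all(c("time_d", "cum_pct") %in% names(data)))

  if (pool_replicates) {
    obs <- dplyr::arrange(dplyr::tibble(time_d = data$time_d,
                                        cum_pct = data$cum_pct), .data$time_d)
  } else {
    obs <- data |>
      dplyr::group_by(.data$time_d) |>
      dplyr::summarise(cum_pct = mean(.data$cum_pct), .groups = "drop") |>
      dplyr::arrange(.data$time_d)
  }
  times <- obs$time_d
  means <- obs$cum_pct
  if (any(means < 0 | means > 100)) {
    abort("observations must lie in [0, 100] % of applied",
          class = "mineralkin_error")
  }

  par_names <- model_par_names(model, fix_mmax)
  p <- length(par_names)
  n_distinct_t <- length(unique(times))
  if (n_distinct_t < p + 2) {
    abort(paste0(model, " fit needs at least ", p + 2,
                 " distinct sampling times, got ", n_distinct_t),
          class = "mineralkin_fit_error")
  }

  bounds <- model_bounds(model, fix_mmax, t_max = max(times))
  start0 <- pmin(pmax(initial_values(model, times, means, fix_mmax),
                      bounds$lower), bounds$upper)
  objective <- function(par) {
    pred <- eval_model(model, times, setNames(par, par_names), 100)
    sum((means - pred)^2)
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(max(n_starts, 1)), function(i) {
      if (i == 1) return(start0)
      jit <- start0 * stats::runif(p, 0.5, 1.5)
      pmin(pmax(jit, bounds$lower), bounds$upper)
    })
  })

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, objective, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 1000, factr = 1e-10 / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(paste0(model, ": all optimizer starts failed"),
          class = "mineralkin_fit_error")
  }

  # L-BFGS-B stalls short of machine precision on near-zero-residual data;
  # polish the winner with a derivative-free pass inside the box. The polish
  # reaching its relative tolerance is the stationarity signal (the gradient
  # codes of the multi-start runs are unreliable at tiny residuals).
  stationary <- FALSE
  if (p >= 2) {
    polish <- tryCatch(
      optim(best$par, objective, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(polish)) {
      stationary <- polish$convergence == 0
      clamped <- pmin(pmax(polish$par, bounds$lower), bounds$upper)
      val <- objective(clamped)
      if (val < best$value) {
        best$par <- clamped
        best$value <- val
      }
    }
  } else {
    polish <- tryCatch(
      optim(best$par, objective, method = "Brent",
            lower = bounds$lower, upper = bounds$upper),
      error = function(e) NULL
    )
    if (!is.null(polish)) {
      stationary <- TRUE
      if (polish$value < best$value) {
        best$par <- polish$par
        best$value <- polish$value
      }
    }
  }

  par <- setNames(best$par, par_names)
  # A rate/shape parameter pinned to its box is not a trustworthy optimum.
  rate_names <- setdiff(par_names, "m_max")
  at_bound <- par[rate_names] <= bounds$lower[rate_names] * (1 + 1e-9) |
    par[rate_names] >= bounds$upper[rate_names] * (1 - 1e-9)
  converged <- stationary && !any(at_bound)

  params <- par_to_kin_params(model, par, 100)
  pred <- eval_model(model, times, par, 100)
  residuals <- means - pred
  # An all-zero curve (abiotic control) has no defined chi2 error level.
  chi2 <- if (mean(means) > 0) chi2_error_percent(means, pred, n_params = p) else NA_real_

  dt50 <- suppressWarnings(dt_x(params, 50, method = "closed_form", basis = basis))
  dt90 <- suppressWarnings(dt_x(params, 90, method = "closed_form", basis = basis))

  structure(list(
    model = model,
    params = params,
    dt50 = dt50$value, dt90 = dt90$value, dt_basis = basis,
    chi2_error_pct = chi2,
    ssr = best$value,
    n_obs = length(times), n_params = p,
    mean_observed = mean(means),
    times = times, observed = means, fitted = pred, residuals = residuals,
    extent_observed = means[length(means)],
    converged = converged, bound_active = any(at_bound),
    n_starts_tried = length(starts), seed = seed,
    fix_mmax = fix_mmax, pool_replicates = pool_replicates
  ), class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("<kin_fit> ", x$model,
      sprintf(" | DT50 %.4g d | chi2 err %.2f%% | extent %.1f%% | %s\n",
              x$dt50, x$chi2_error_pct, x$extent_observed,
              if (x$converged) "converged" else "NOT converged"), sep = "")
  print(x$params)
  invisible(x)
}

#' Select the best kinetic model by chi-square error
#'
#' Returns the converged fit with the smallest FOCUS chi-square error
#' percentage. Ties within 0.1 percentage points are broken towards the model
#' with fewer parameters. A winning fit whose error is at or above 15% is
#' flagged `poor_fit` (the conventional acceptability threshold), never
#' dropped.
#'
#' @param fits A list of [fit_kinetics()] results for the same curve.
#' @return The selected `kin_fit`, with a `poor_fit` field added.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "kin_fit")) fits <- list(fits)
  if (length(fits) == 0) {
    abort("no fits supplied", class = "mineralkin_error")
  }
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) == 0) {
    abort("no converged fit to select from", class = "mineralkin_fit_error")
  }
  err <- vapply(ok, function(f) f$chi2_error_pct, numeric(1))
  npar <- vapply(ok, function(f) f$n_params, numeric(1))
  near <- err <= min(err) + 0.1
  pick <- which(near)[order(npar[near], err[near])][1]
  best <- ok[[pick]]
  best$poor_fit <- best$chi2_error_pct >= 15
  best
}

#' Fit and select kinetic models for every curve in a study
#'
#' The batch driver: for each `soil` x `treatment` group, fits the requested
#' models and keeps the [select_model()] winner. Per-curve failures are
#' recorded (`error` column) and the batch continues.
#'
#' @param data Long study tibble with columns `soil`, `treatment`,
#'   `replicate`, `time_d`, `cum_pct` (the [read_curves_csv()] /
#'   [simulate_study()] schema).
#' @param models Models to try; default all three.
#' @param ... Passed to [fit_kinetics()] (e.g. `fix_mmax`, `seed`, `basis`).
#' @return A tibble, one row per soil x treatment, with the selected model's
#'   parameters, DT50/DT90, observed extent, chi-square error, flags, and the
#'   full `kin_fit` in a `fit` list-column. Ordered by soil then treatment.
#' @examples
#' study <- simulate_study(study_config(truth = published_truth()[1:2, ], seed = 1))
#' fits <- fit_study(study, seed = 1)
#' @export
fit_study <- function(data, models = c("SFO", "FOMC", "HS"), ...) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    return(tibble::tibble(soil = character(), treatment = character(),
                          model = character(), k1 = double(), k2 = double(),
                          tb = double(), alpha = double(), beta = double(),
                          m_max = double(), dt50 = double(), dt90 = double(),
                          extent_pct = double(), chi2_error_pct = double(),
                          converged = logical(), poor_fit = logical(),
                          error = character(), fit = list()))
  }
  data |>
    dplyr::group_by(.data$soil, .data$treatment) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$soil, .data$treatment) |>
    dplyr::mutate(res = purrr::map(.data$data, fit_one_curve,
                                   models = models, ...)) |>
    dplyr::select(-"data") |>
    tidyr::unnest("res")
}

fit_one_curve <- function(curve, models, ...) {
  sel <- tryCatch({
    fits <- lapply(models, function(m) {
      tryCatch(fit_kinetics(curve, model = m, ...), error = function(e) NULL)
    })
    select_model(Filter(Negate(is.null), fits))
  }, error = function(e) e)
  if (inherits(sel, "error")) {
    return(tibble::tibble(model = NA_character_, k1 = NA_real_, k2 = NA_real_,
                          tb = NA_real_, alpha = NA_real_, beta = NA_real_,
                          m_max = NA_real_, dt50 = NA_real_, dt90 = NA_real_,
                          extent_pct = NA_real_, chi2_error_pct = NA_real_,
                          converged = FALSE, poor_fit = NA,
                          error = conditionMessage(sel), fit = list(NULL)))
  }
  p <- sel$params
  tibble::tibble(
    model = sel$model,
    k1 = p$k1 %||% NA_real_, k2 = p$k2 %||% NA_real_, tb = p$tb %||% NA_real_,
    alpha = p$alpha %||% NA_real_, beta = p$beta %||% NA_real_,
    m_max = p$m_max,
    dt50 = sel$dt50, dt90 = sel$dt90,
    extent_pct = sel$extent_observed,
    chi2_error_pct = sel$chi2_error_pct,
    converged = sel$converged, poor_fit = sel$poor_fit,
    error = NA_character_, fit = list(sel)
  )
}
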