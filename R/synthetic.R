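# Synthetic 14C-PHE respirometry: triplicate alkali-trap curves with additive
# scintillation-counting noise, standing in for raw study data.

# Default sampling schedule: dense early, 120-day horizon.
default_schedule <- function() c(0, 1, 3, 7, 10, 14, 17, 21, 28, 35, 42, 60, 80, 100, 120)

#' Configuration for a synthetic mineralization study
#'
#' Bundles the experimental structure of a slurry respirometry study: soils x
#' treatments with a truth kinetic model each, a sampling schedule, replicate
#' count, an additive noise model, and the applied dose bookkeeping
#' (450 Bq of \eqn{^{14}}C-phenanthrene and 50 mg kg^-1 total per flask).
#'
#' @param truth A tibble mapping each curve to its generating model:
#'   columns `soil`, `treatment`, `model`, and the parameter columns
#'   `k1`, `k2`, `tb`, `alpha`, `beta`, `m_max` (unused entries `NA`).
#'   See [published_truth()] and [abiotic_truth()] for shipped presets.
#' @param schedule Sampling times in days; strictly increasing, starting at 0.
#' @param replicates Flasks per soil x treatment (study default 3).
#' @param noise_sd Additive noise standard deviation, % of applied (default
#'   1.5 — scintillation counting error is roughly absolute).
#' @param noise_mode `"cumulative_gaussian"` (noise on cumulative values,
#'   monotonicity restored by running maximum) or `"increment_gaussian"`
#'   (noise on inter-sample increments, floored at zero, then cumulated).
#' @param applied_activity Applied activity per flask, Bq.
#' @param applied_conc Applied phenanthrene concentration, mg kg^-1.
#' @param seed Master seed; per-curve child seeds are derived from it.
#' @return A `study_config` list.
#' @export
study_config <- function(truth,
                         schedule = default_schedule(),
                         replicates = 3,
                         noise_sd = 1.5,
                         noise_mode = c("cumulative_gaussian", "increment_gaussian"),
                         applied_activity = 450,
                         applied_conc = 50,
                         seed = 1) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(is.data.frame(truth))
  need <- c("soil", "treatment", "model")
  if (!all(need %in% names(truth))) {
    abort("truth map needs columns soil, treatment, model (+ parameters)",
          class = "mineralkin_config_error")
  }
  check_schedule(schedule)
  if (replicates < 1) {
    abort("'replicates' must be >= 1", class = "mineralkin_config_error")
  }
  if (noise_sd < 0) {
    abort("'noise_sd' must be >= 0", class = "mineralkin_config_error")
  }
  if (applied_activity <= 0) {
    abort("'applied_activity' must be > 0", class = "mineralkin_config_error")
  }
  structure(list(truth = tibble::as_tibble(truth), schedule = as.numeric(schedule),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 noise_mode = noise_mode, applied_activity = applied_activity,
                 applied_conc = applied_conc, seed = as.integer(seed)),
            class = "study_config")
}

check_schedule <- function(schedule) {
  if (length(schedule) < 2 || schedule[1] != 0 || any(diff(schedule) <= 0)) {
    abort("sampling schedule must start at 0 and be strictly increasing",
          class = "mineralkin_config_error")
  }
  invisible(schedule)
}

#' Simulate one replicated mineralization curve
#'
#' Evaluates the truth model at the schedule times and adds measurement noise
#' per replicate. With `noise_mode = "cumulative_gaussian"`, i.i.d. Gaussian
#' noise is added to the cumulative percentages and physical cumulativity is
#' restored with a running maximum (a mild truncation of the noise
#' distribution); with `"increment_gaussian"`, the inter-sample increments are
#' perturbed, floored at zero and re-cumulated. Either way the trap starts
#' empty: the value at t = 0 is exactly 0, and values are clipped to
#' \eqn{[0, 100]}.
#'
#' @param truth A [kin_params()] object (the generating model).
#' @param schedule Sampling times, days, starting at 0.
#' @param replicates Number of replicate flasks.
#' @param noise_sd Additive noise SD, % of applied.
#' @param noise_mode See [study_config()].
#' @param seed Integer seed; the same seed reproduces the curve exactly.
#' @param soil,treatment Labels carried into the output.
#' @return A long tibble: `soil`, `treatment`, `replicate`, `time_d`,
#'   `cum_pct`, `provenance` (= `"synthetic"`).
#' @examples
#' simulate_curve(kin_params("SFO", k1 = 0.02, m_max = 40), seed = 7)
#' @export
simulate_curve <- function(truth, schedule = default_schedule(), replicates = 3,
                           noise_sd = 1.5,
                           noise_mode = c("cumulative_gaussian", "increment_gaussian"),
                           seed = 1, soil = "S1", treatment = "A") {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(truth, "kin_params"))
  check_schedule(schedule)
  clean <- kin_curve(schedule, truth)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      n <- length(schedule)
      if (noise_sd == 0) {
        vals <- clean
      } else if (noise_mode == "cumulative_gaussian") {
        vals <- clean + c(0, rnorm(n - 1, 0, noise_sd))
        vals <- cummax(pmin(pmax(vals, 0), 100))
      } else {
        inc <- pmax(diff(clean) + rnorm(n - 1, 0, noise_sd), 0)
        vals <- pmin(c(0, cumsum(inc)), 100)
      }
      tibble::tibble(replicate = r, time_d = schedule, cum_pct = vals)
    })
  })
  dplyr::bind_rows(reps) |>
    dplyr::mutate(soil = soil, treatment = treatment, provenance = "synthetic",
                  .before = 1)
}

# Deterministic, collision-free child seed below 2^31.
child_seed <- function(master, index) {
  (as.integer(master) %% 1000003L) * 2017L + index * 7919L
}

#' Simulate a full mineralization study
#'
#' One replicated curve per row of the configuration's truth map, with child
#' seeds derived deterministically from the master seed so the whole study is
#' reproducible and curves are independent.
#'
#' @param config A [study_config()].
#' @return A long tibble in the standard curve schema (`soil`, `treatment`,
#'   `replicate`, `time_d`, `cum_pct`, `provenance`).
#' @examples
#' study <- simulate_study(study_config(truth = published_truth(), seed = 1))
#' dplyr::count(study, soil, treatment)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- seq_len(nrow(config$truth))
  purrr::map_dfr(rows, function(i) {
    row <- config$truth[i, ]
    simulate_curve(truth_row_params(row),
                   schedule = config$schedule,
                   replicates = config$replicates,
                   noise_sd = config$noise_sd,
                   noise_mode = config$noise_mode,
                   seed = child_seed(config$seed, i),
                   soil = row$soil, treatment = row$treatment)
  })
}

# Build kin_params from one truth-map row; missing entries are a config error.
truth_row_params <- function(row) {
  g <- function(nm) {
    v <- row[[nm]] %||% NA_real_
    if (is.na(v)) NULL else v
  }
  m_max <- row[["m_max"]] %||% 100
  if (is.na(m_max)) m_max <- 100
  tryCatch(
    kin_params(row$model, k1 = g("k1"), k2 = g("k2"), tb = g("tb"),
               alpha = g("alpha"), beta = g("beta"), m_max = m_max),
    error = function(e) {
      abort(paste0("truth map row ", row$soil, "/", row$treatment,
                   " is incomplete for ", row$model, ": ", conditionMessage(e)),
            class = "mineralkin_config_error")
    }
  )
}

#' Convert trapped activity to cumulative percent of applied
#'
#' Alkali-trap arithmetic: each trap sample removes the \eqn{^{14}CO_2}
#' captured since the previous sampling, so the cumulative mineralization is
#' the running sum of trap measurements over the applied activity.
#'
#' @param trapped Bq measured in successive trap samples (non-negative).
#' @param applied Applied activity per flask, Bq (study default 450).
#' @return Cumulative % of applied, same length as `trapped`.
#' @examples
#' bq_to_percent(c(45, 45, 90))  # 10, 20, 40 % of 450 Bq
#' @export
bq_to_percent <- function(trapped, applied = 450) {
  if (any(trapped < 0)) {
    abort("trapped activity must be >= 0", class = "mineralkin_error")
  }
  if (applied <= 0) {
    abort("applied activity must be > 0", class = "mineralkin_error")
  }
  pct <- cumsum(trapped) / applied * 100
  if (any(pct > 100)) {
    abort("cumulative recovery exceeds 100% of applied: mass balance violated",
          class = "mineralkin_error")
  }
  pct
}
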