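#' Tidy a kinetic model fit
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return One row per fitted parameter: `term`, `estimate`.
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  p <- x$params
  est <- unlist(p[setdiff(names(p), "model")])
  if (x$fix_mmax) est <- est[names(est) != "m_max"]
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' Glance at a kinetic model fit
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return A one-row tibble: model, DT50/DT90 (days), FOCUS chi-square error
#'   (%), SSR, observed extent, counts and convergence flags.
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(model = x$model, dt50 = x$dt50, dt90 = x$dt90,
                 chi2_error_pct = x$chi2_error_pct, ssr = x$ssr,
                 n_obs = x$n_obs, n_params = x$n_params,
                 mean_observed = x$mean_observed,
                 extent_observed = x$extent_observed,
                 converged = x$converged, poor_fit = x$poor_fit %||% NA,
                 n_starts_tried = x$n_starts_tried, seed = x$seed)
}

#' Augment: observed, fitted and residuals per sampling time
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return A tibble with `time_d`, `observed`, `fitted`, `residual`.
#' @method augment kin_fit
#' @export
augment.kin_fit <- function(x, ...) {
  tibble::tibble(time_d = x$times, observed = x$observed,
                 fitted = x$fitted, residual = x$residuals)
}

#' Plot observed versus fitted mineralization curve
#'
#' @param object A [fit_kinetics()] result.
#' @param ... Unused.
#' @return A ggplot: observed replicate means (points) and the fitted model
#'   curve (line) over the study horizon.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, ...) {
  grid <- tibble::tibble(time_d = seq(0, max(object$times), length.out = 200))
  grid$fitted <- kin_curve(grid$time_d, object$params)
  ggplot2::ggplot(augment(object), ggplot2::aes(x = .data$time_d)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "Time (d)", y = "Cumulative mineralization (% of applied)",
                  title = sprintf("%s fit: DT50 = %.3g d, chi2 err = %.2f%%",
                                  object$model, object$dt50,
                                  object$chi2_error_pct)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot all curves of a study, faceted by soil
#'
#' @param data A curve tibble (see [simulate_study()] / [read_curves_csv()]).
#' @return A ggplot of replicate-mean curves coloured by treatment.
#' @export
plot_study_curves <- function(data) {
  means <- data |>
    dplyr::group_by(.data$soil, .data$treatment, .data$time_d) |>
    dplyr::summarise(cum_pct = mean(.data$cum_pct), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$time_d, y = .data$cum_pct,
                                      colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~soil) +
    ggplot2::labs(x = "Time (d)", y = "Cumulative mineralization (% of applied)",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}
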