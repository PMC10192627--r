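# Curve CSV schema (long/tidy): soil,treatment,replicate,time_d,cum_pct
curve_cols <- c("soil", "treatment", "replicate", "time_d", "cum_pct")

#' Read mineralization curves from a long-format CSV
#'
#' Expects columns `soil,treatment,replicate,time_d,cum_pct` (comma-separated,
#' dot decimal). Validates on read: percentages in \eqn{[0, 100]}, a 0% value
#' at t = 0 for every replicate, no duplicate (soil, treatment, replicate,
#' time) rows, and cumulative values non-decreasing within each replicate up
#' to a 0.5% measurement tolerance. Replicates need not be balanced.
#'
#' @param path CSV file path.
#' @return A curve tibble (`provenance = "file"`).
#' @export
read_curves_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(curve_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("curve CSV is missing columns: ", paste(missing, collapse = ", ")),
          class = "mineralkin_validation_error")
  }
  df <- dplyr::mutate(df, soil = as.character(.data$soil),
                      treatment = as.character(.data$treatment),
                      replicate = as.integer(.data$replicate),
                      time_d = as.numeric(.data$time_d),
                      cum_pct = as.numeric(.data$cum_pct))
  validate_curves(df)
  dplyr::mutate(df[curve_cols], provenance = "file")
}

#' Validate a curve tibble against the schema invariants
#'
#' @param df A curve tibble.
#' @param monotone_tol Allowed backward step in cumulative %, per replicate.
#' @return `df`, invisibly, if valid; otherwise a validation error listing the
#'   offending rows.
#' @export
validate_curves <- function(df, monotone_tol = 0.5) {
  bad_range <- which(!is.finite(df$cum_pct) | df$cum_pct < 0 | df$cum_pct > 100)
  if (length(bad_range) > 0) {
    abort(paste0("cum_pct outside [0, 100] at rows: ",
                 paste(head(bad_range, 10), collapse = ", ")),
          class = "mineralkin_validation_error")
  }
  dup <- duplicated(df[curve_cols[1:4]])
  if (any(dup)) {
    abort(paste0("duplicate (soil, treatment, replicate, time) rows: ",
                 paste(head(which(dup), 10), collapse = ", ")),
          class = "mineralkin_validation_error")
  }
  chk <- df |>
    dplyr::group_by(.data$soil, .data$treatment, .data$replicate) |>
    dplyr::arrange(.data$time_d, .by_group = TRUE) |>
    dplyr::mutate(drop = .data$cum_pct - cummax(.data$cum_pct)) |>
    dplyr::ungroup()
  if (any(chk$drop < -monotone_tol)) {
    bad <- chk |>
      dplyr::filter(.data$drop < -monotone_tol) |>
      dplyr::mutate(row = paste0(.data$soil, "/", .data$treatment, " rep ",
                                 .data$replicate, " t=", .data$time_d))
    abort(paste0("cumulative values decrease beyond tolerance at: ",
                 paste(head(bad$row, 10), collapse = "; ")),
          class = "mineralkin_validation_error")
  }
  t0 <- df |>
    dplyr::group_by(.data$soil, .data$treatment, .data$replicate) |>
    dplyr::summarise(t0 = min(.data$time_d), v0 = .data$cum_pct[which.min(.data$time_d)],
                     .groups = "drop")
  if (any(t0$t0 != 0) || any(t0$v0 > monotone_tol)) {
    abort("every replicate needs a t = 0 observation with 0% recovered",
          class = "mineralkin_validation_error")
  }
  invisible(df)
}

#' @rdname read_curves_csv
#' @param df Curve tibble to write.
#' @export
write_curves_csv <- function(df, path) {
  readr::write_csv(df[intersect(curve_cols, names(df))], path)
  invisible(path)
}

# ---- Publication-style fit report ------------------------------------------

fmt_rate <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.1e", signif(x, 2)))
}

fmt_days <- function(x) {
  dplyr::case_when(
    is.na(x) ~ "-",
    is.infinite(x) | x > 1e7 ~ ">10^7",
    x >= 100 ~ sprintf("%.0f", x),
    TRUE ~ sprintf("%.1f", x)
  )
}

fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))

#' Format a fitted study as a publication-style kinetics table
#'
#' One row per soil x treatment with the selected model and its parameters:
#' rates to two significant figures in scientific notation, dissipation times
#' to whole days at or above 100 d (one decimal below), dashes for parameters
#' the selected model does not use, and the sentinel `">10^7"` for
#' unreachable DT50 targets. Ordering is soil, then treatment.
#'
#' @param fits The [fit_study()] result tibble.
#' @return A character tibble with columns `soil`, `treatment`,
#'   `kinetic_model`, `k1`, `k2`, `tb`, `alpha`, `beta`, `dt50`,
#'   `extent_pct`, `chi2_error_pct`.
#' @export
format_fit_table <- function(fits) {
  fits |>
    dplyr::arrange(.data$soil, .data$treatment) |>
    dplyr::transmute(
      soil = .data$soil, treatment = .data$treatment,
      kinetic_model = ifelse(is.na(.data$model), "-", .data$model),
      k1 = fmt_rate(.data$k1), k2 = fmt_rate(.data$k2),
      tb = fmt_days(.data$tb),
      alpha = ifelse(is.na(.data$alpha), "-", sprintf("%.2g", .data$alpha)),
      beta = fmt_days(.data$beta),
      dt50 = fmt_days(.data$dt50),
      extent_pct = fmt_pct(.data$extent_pct),
      chi2_error_pct = fmt_pct(.data$chi2_error_pct)
    )
}

#' Write the fit report table to CSV or Markdown
#'
#' @param fits The [fit_study()] result tibble.
#' @param path Output file.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  tab <- format_fit_table(fits)
  if (format == "csv") {
    readr::write_csv(tab, path)
  } else {
    writeLines(md_table(tab), path)
  }
  invisible(path)
}

md_table <- function(tab) {
  hdr <- names(tab)
  body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
    body)
}

#' Write a Markdown study report
#'
#' Summarizes a fitted study: the kinetics table plus, per soil, the
#' treatments ranked by DT50 (fastest dissipation first) with their observed
#' mineralization extents.
#'
#' @param fits The [fit_study()] result tibble.
#' @param path Output Markdown file.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(fits, path) {
  lines <- c("# Mineralization kinetics report", "",
             "## Fitted kinetic parameters", "",
             md_table(format_fit_table(fits)), "",
             "## DT50 ranking per soil (fastest first)", "")
  ranked <- fits |>
    dplyr::filter(!is.na(.data$dt50)) |>
    dplyr::arrange(.data$soil, .data$dt50)
  for (s in unique(ranked$soil)) {
    sub <- ranked[ranked$soil == s, ]
    lines <- c(lines, paste0("- **", s, "**: ",
      paste(sprintf("%s (DT50 %s d, extent %.1f%%)", sub$treatment,
                    fmt_days(sub$dt50), sub$extent_pct), collapse = "; ")))
  }
  writeLines(lines, path)
  invisible(path)
}
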