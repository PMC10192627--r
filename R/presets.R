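# Shipped truth maps for the synthetic generator.

#' Truth map presets for the synthetic respirometry generator
#'
#' `published_truth()` returns the published per-soil, per-treatment kinetic
#' parameters of the five-soil phenanthrene slurry study (soils PLD, LL, ALC,
#' CR, R; treatments A = untreated control, B = nutrient solution (NS),
#' C = HPBCD + NS, D = *S. indicatrix* CPHE1 + NS, E = strain + HPBCD + NS),
#' usable as the `truth` argument of [study_config()] so a full 25-curve
#' study with realistic kinetics can be regenerated. Amplitudes are set to
#' 100% of applied: the published extents are observations at 120 days, not
#' model plateaus.
#'
#' `abiotic_truth()` is the sterilized-control preset: all rates zero-like
#' (k1 at the numerical floor), producing flat 0% curves — abiotic
#' dissipation of phenanthrene is not expected on this time scale.
#'
#' @param soils Subset of soils to keep.
#' @param treatments Subset of treatments A–E to keep.
#' @return A tibble with columns `soil`, `treatment`, `model`, `k1`, `k2`,
#'   `tb`, `alpha`, `beta`, `m_max`.
#' @examples
#' published_truth(soils = "CR", treatments = c("B", "C"))
#' @export
published_truth <- function(soils = NULL, treatments = NULL) {
  tab <- read_truth_yaml(system.file("extdata", "published_study_truth.yaml",
                                     package = "mineralkin", mustWork = TRUE))
  if (!is.null(soils)) tab <- dplyr::filter(tab, .data$soil %in% soils)
  if (!is.null(treatments)) tab <- dplyr::filter(tab, .data$treatment %in% treatments)
  tab
}

#' @rdname published_truth
#' @export
abiotic_truth <- function(soils = c("PLD", "LL", "ALC", "CR", "R")) {
  tibble::tibble(soil = soils, treatment = "abiotic", model = "SFO",
                 k1 = 1e-12, k2 = NA_real_, tb = NA_real_,
                 alpha = NA_real_, beta = NA_real_, m_max = 100)
}

#' Read a truth map from a YAML study configuration
#'
#' The shipped preset (and any user config) is a YAML list of curve entries,
#' each with `soil`, `treatment`, `model` and the model's parameters.
#'
#' @param path Path to the YAML file.
#' @return A truth-map tibble (see [published_truth()]).
#' @export
read_truth_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- raw$curves %||% raw
  purrr::map_dfr(entries, function(e) {
    tibble::tibble(
      soil = as.character(e$soil), treatment = as.character(e$treatment),
      model = toupper(e$model),
      k1 = as.numeric(e$k1 %||% NA), k2 = as.numeric(e$k2 %||% NA),
      tb = as.numeric(e$tb %||% NA),
      alpha = as.numeric(e$alpha %||% NA), beta = as.numeric(e$beta %||% NA),
      m_max = as.numeric(e$m_max %||% 100)
    )
  })
}
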