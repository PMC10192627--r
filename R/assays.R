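# Assay arithmetic: serial-dilution plate counts, extractability percentages
# and cyclodextrin dosing. All exactly linear in their leading input.

#' Colony-forming units per gram of soil from serial-dilution plate counts
#'
#' Standard plate-count back-calculation for the 1 g soil : 5 mL suspension
#' protocol with 1:10 serial dilutions and 100 uL plated:
#' \deqn{CFU\,g^{-1} = \frac{colonies}{V_{plated}} \times 10^{d} \times \frac{V_{susp}}{m_{soil}}}
#' The suspension-volume/soil-mass factor is exposed so alternative
#' normalization conventions can be reproduced.
#'
#' @param data A data frame with a `colonies` column (counts per plate) and a
#'   `dilution_exponent` column (plate from the \eqn{10^{-d}} dilution);
#'   optional per-row overrides `plated_volume_ml`, `suspension_volume_ml`,
#'   `soil_mass_g`.
#' @param plated_volume_ml,suspension_volume_ml,soil_mass_g Defaults used
#'   where the data frame has no override column (0.1 mL plated, 5 mL
#'   suspension, 1 g soil).
#' @return The input as a tibble with a `cfu_per_g` column appended.
#' @examples
#' cfu_per_gram(tibble::tibble(colonies = 30, dilution_exponent = 4))
#' @export
cfu_per_gram <- function(data, plated_volume_ml = 0.1,
                         suspension_volume_ml = 5, soil_mass_g = 1) {
  stopifnot(is.data.frame(data),
            all(c("colonies", "dilution_exponent") %in% names(data)))
  df <- tibble::as_tibble(data)
  vp <- df[["plated_volume_ml"]] %||% plated_volume_ml
  vs <- df[["suspension_volume_ml"]] %||% suspension_volume_ml
  ms <- df[["soil_mass_g"]] %||% soil_mass_g
  if (any(df$colonies < 0) || any(df$dilution_exponent < 0) ||
      any(vp <= 0) || any(vs <= 0) || any(ms <= 0)) {
    abort("colonies/dilution must be >= 0 and volumes/mass > 0",
          class = "mineralkin_error")
  }
  dplyr::mutate(df, cfu_per_g = (.data$colonies / vp) *
                  10^.data$dilution_exponent * vs / ms)
}

#' Percent of applied phenanthrene recovered in a soil extract
#'
#' Availability assay arithmetic for the 1 g soil / 5 mL extractant protocol:
#' mass in the extract (`conc x volume`) over the applied mass, as a percent.
#' Recovery above 100% violates mass balance and is an error.
#'
#' @param data A data frame with `extract_conc_mg_l`; optional per-row
#'   `extract_volume_ml` and `applied_mass_mg` overrides.
#' @param extract_volume_ml Default extract volume, mL.
#' @param applied_mass_mg Default applied mass, mg (0.05 mg = 50 mg kg^-1 in
#'   1 g of soil).
#' @return The input as a tibble with a `percent_extracted` column appended.
#' @examples
#' percent_extracted(tibble::tibble(soil = "CR", extractant = "NS_HPBCD",
#'                                  extract_conc_mg_l = 1.88))
#' @export
percent_extracted <- function(data, extract_volume_ml = 5, applied_mass_mg = 0.05) {
  stopifnot(is.data.frame(data), "extract_conc_mg_l" %in% names(data))
  df <- tibble::as_tibble(data)
  vol <- df[["extract_volume_ml"]] %||% extract_volume_ml
  applied <- df[["applied_mass_mg"]] %||% applied_mass_mg
  if (any(applied <= 0)) {
    abort("applied mass must be > 0", class = "mineralkin_error")
  }
  if (any(df$extract_conc_mg_l < 0)) {
    abort("extract concentration must be >= 0", class = "mineralkin_error")
  }
  pct <- df$extract_conc_mg_l * (vol / 1000) / applied * 100
  if (any(pct > 100)) {
    abort("extracted more than 100% of applied: mass balance violated",
          class = "mineralkin_error")
  }
  dplyr::mutate(df, percent_extracted = pct)
}

#' Read extraction records from CSV
#'
#' Schema: `soil,extractant,conc_mg_L,volume_mL` (volume optional).
#'
#' @param path CSV path.
#' @return Tibble with standardized columns ready for [percent_extracted()].
#' @export
read_extractions_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("soil", "extractant", "conc_mg_L") %in% names(df))) {
    abort("extraction CSV needs columns soil, extractant, conc_mg_L",
          class = "mineralkin_validation_error")
  }
  tibble::tibble(soil = as.character(df$soil),
                 extractant = as.character(df$extractant),
                 extract_conc_mg_l = as.numeric(df$conc_mg_L),
                 extract_volume_ml = as.numeric(df[["volume_mL"]] %||% 5))
}

#' Hydroxypropyl-beta-cyclodextrin dose for a target molar ratio
#'
#' Mass of HPBCD delivering `molar_ratio` times the moles of applied
#' phenanthrene (protocol: 10x the initial molar concentration):
#' \deqn{m_{HPBCD} = \frac{c_{applied} \, m_{soil} / 1000}{MW_{PHE}} \times ratio \times MW_{HPBCD}}
#'
#' @param applied_conc Applied phenanthrene concentration, mg kg^-1.
#' @param soil_mass_g Soil mass, g.
#' @param molar_ratio HPBCD:PHE molar ratio (default 10).
#' @param mw_phe Molar mass of phenanthrene, g mol^-1.
#' @param mw_hpbcd Molar mass of HPBCD, g mol^-1; 1380 is a typical
#'   substitution grade (the exact grade is product-specific).
#' @return HPBCD mass, mg. Vectorized.
#' @examples
#' hpbcd_dose(50, 10)  # 38.7 mg for a 10 g flask at 50 mg kg^-1
#' @export
hpbcd_dose <- function(applied_conc, soil_mass_g, molar_ratio = 10,
                       mw_phe = 178.23, mw_hpbcd = 1380) {
  if (any(applied_conc < 0) || any(soil_mass_g <= 0) || any(molar_ratio < 0) ||
      any(mw_phe <= 0) || any(mw_hpbcd <= 0)) {
    abort("inputs must be positive (molar_ratio may be 0)",
          class = "mineralkin_error")
  }
  applied_conc * soil_mass_g / 1000 / mw_phe * molar_ratio * mw_hpbcd
}
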