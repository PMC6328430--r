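#' Bundled cohort TIACs from a published [68Ga]PSMA-11 dosimetry study
#'
#' Median and per-patient time-integrated activity coefficients (hours per
#' unit administered activity) for the six-patient low-risk prostate cancer
#' cohort whose dosimetry this package re-implements. The raw images are not
#' public, so these published per-organ TIACs serve as pipeline inputs (e.g.
#' for the dose engine) rather than as quantities the package re-derives.
#' Lacrimal-gland entries are the two-gland totals.
#'
#' @param long Return tidy long format (`patient_id`, `organ`, `tiac_h`)
#'   instead of the organ-by-patient wide table.
#' @return A tibble. Wide: `organ`, `median_h`, `P1`..`P6`. Long: one row per
#'   patient and organ (medians excluded).
#' @examples
#' psma11_cohort_tiacs()
#' @export
psma11_cohort_tiacs <- function(long = FALSE) {
  wide <- tibble::tribble(
    ~organ, ~median_h, ~P1, ~P2, ~P3, ~P4, ~P5, ~P6,
    "kidneys", 0.22, 0.22, 0.27, 0.19, 0.23, 0.19, 0.26,
    "liver", 0.23, 0.26, 0.15, 0.22, 0.23, 0.19, 0.31,
    "spleen", 0.021, 0.049, 0.012, 0.017, 0.026, 0.019, 0.022,
    "salivary_glands", 0.020, 0.036, 0.020, 0.021, 0.017, 0.030, 0.017,
    "urinary_bladder_contents", 0.11, 0.12, 0.094, 0.13, 0.041, 0.16, 0.050,
    "blood", 0.27, 0.32, 0.26, 0.36, 0.22, 0.25, 0.28,
    "remainder", 0.68, 0.51, 0.76, 0.62, 0.78, 0.73, 0.63,
    "lacrimal_glands", 0.00053, 0.00075, 0.00055, 0.00038, 0.00093,
    0.00052, 0.00020
  )
  if (!long) return(wide)
  tidyr::pivot_longer(dplyr::select(wide, -"median_h"),
                      cols = dplyr::starts_with("P"),
                      names_to = "patient_id", values_to = "tiac_h")
}

#' Bundled organ absorbed-dose coefficients from the same published cohort
#'
#' Cohort-median absorbed-dose coefficients (mGy/MBq) and per-patient ranges
#' for [68Ga]PSMA-11, as reported for the six-patient study the package
#' re-implements. Used as the input for effective-dose weighting and as
#' consistency anchors for the simplified dose engine.
#'
#' The eye-lens range is stored as (0.0054, 0.0067): the source table prints
#' the two bounds in reversed order, and its median (0.0051) lies outside
#' them - kept as printed values, low bound first.
#'
#' @return A tibble with columns `organ`, `median_mGy_per_MBq`,
#'   `range_low_mGy_per_MBq`, `range_high_mGy_per_MBq`.
#' @examples
#' psma11_dose_coefficients()
#' @export
psma11_dose_coefficients <- function() {
  tibble::tribble(
    ~organ, ~median_mGy_per_MBq, ~range_low_mGy_per_MBq, ~range_high_mGy_per_MBq,
    "kidneys", 0.24, 0.20, 0.28,
    "liver", 0.053, 0.038, 0.071,
    "lungs", 0.016, 0.013, 0.017,
    "spleen", 0.046, 0.030, 0.10,
    "salivary_glands", 0.089, 0.074, 0.15,
    "urinary_bladder_wall", 0.057, 0.028, 0.084,
    "endosteum", 0.011, 0.0095, 0.011,
    "red_bone_marrow", 0.015, 0.014, 0.015,
    "lacrimal_glands", 0.11, 0.043, 0.2,
    "eye_lenses", 0.0051, 0.0054, 0.0067,
    "stomach_wall", 0.015, 0.015, 0.017,
    "colon_wall", 0.014, 0.012, 0.014,
    "esophagus", 0.014, 0.011, 0.015,
    "skin", 0.0067, 0.0059, 0.0069,
    "testes", 0.0087, 0.0074, 0.0089,
    "thyroid", 0.010, 0.0090, 0.010
  )
}
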