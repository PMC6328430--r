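#' Convert activity-concentration samples to fractions of injected activity
#'
#' Implements the retention relation U(t) = C_median(t) x M / A0: an organ's
#' median activity concentration (Bq/mL, unit tissue density) times the
#' reference organ mass, divided by the administered activity, giving the
#' dimensionless fraction of injected activity. The `decay_corrected` flag of
#' each sample is preserved untouched.
#'
#' @param samples Data frame of activity samples with columns `patient_id`,
#'   `organ`, `time_min`, `value`, `value_kind`, `decay_corrected`. Rows with
#'   `value_kind == "fraction_injected"` pass through unchanged.
#' @param organ_masses Data frame with columns `organ` and `mass_g` (e.g.
#'   [reference_organ_masses()]), or a named numeric vector of gram masses.
#' @param administered_Bq Administered activity in Bq. Either a single value
#'   or a data frame with columns `patient_id` and `administered_Bq` (or
#'   `administered_MBq`).
#' @return A tibble shaped like `samples` with `value` as a fraction of
#'   injected activity and `value_kind = "fraction_injected"`. Fractions above
#'   1 are kept but flagged with a warning.
#' @examples
#' s <- tibble::tibble(patient_id = "P1", organ = "kidneys", time_min = 90,
#'                     value = 1000, value_kind = "concentration_Bq_per_mL",
#'                     decay_corrected = TRUE)
#' fraction_injected_activity(s, c(kidneys = 422), administered_Bq = 155e6)
#' @export
fraction_injected_activity <- function(samples, organ_masses, administered_Bq) {
  samples <- validate_activity_samples(samples)
  masses <- as_mass_table(organ_masses)
  if (is.data.frame(administered_Bq)) {
    adm <- tibble::as_tibble(administered_Bq)
    if (!"administered_Bq" %in% names(adm) && "administered_MBq" %in% names(adm)) {
      adm$administered_Bq <- adm$administered_MBq * 1e6
    }
    stopifnot(all(c("patient_id", "administered_Bq") %in% names(adm)))
    samples <- dplyr::left_join(samples,
                                dplyr::select(adm, "patient_id", "administered_Bq"),
                                by = "patient_id")
  } else {
    samples$administered_Bq <- administered_Bq
  }
  if (any(!is.finite(samples$administered_Bq)) || any(samples$administered_Bq <= 0)) {
    abort("administered activity must be positive for every sample.",
          class = "psmadosim_domain_error")
  }
  out <- dplyr::left_join(samples, masses, by = "organ")
  if (anyNA(out$mass_g)) {
    missing <- unique(out$organ[is.na(out$mass_g)])
    abort(paste0("No organ mass supplied for: ", paste(missing, collapse = ", ")),
          class = "psmadosim_missing_mass")
  }
  conc <- out$value_kind == "concentration_Bq_per_mL"
  out$value[conc] <- out$value[conc] * out$mass_g[conc] / out$administered_Bq[conc]
  out$value_kind[conc] <- "fraction_injected"
  if (any(out$value > 1)) {
    warn(sprintf("%d retention value(s) exceed 1; kept as-is.", sum(out$value > 1)))
  }
  dplyr::select(out, -"mass_g", -"administered_Bq")
}

#' Validate a table of activity samples
#'
#' @param samples Data frame with columns `patient_id`, `organ`, `time_min`,
#'   `value`, `value_kind` (`"concentration_Bq_per_mL"` or
#'   `"fraction_injected"`), `decay_corrected` (logical).
#' @return The samples as a tibble; errors on schema violations.
#' @export
validate_activity_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  req <- c("patient_id", "organ", "time_min", "value", "value_kind",
           "decay_corrected")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    abort(paste0("samples are missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(samples$time_min < 0) || any(samples$value < 0)) {
    abort("time_min and value must be nonnegative.",
          class = "psmadosim_domain_error")
  }
  ok_kind <- samples$value_kind %in% c("concentration_Bq_per_mL", "fraction_injected")
  if (!all(ok_kind)) {
    abort("value_kind must be 'concentration_Bq_per_mL' or 'fraction_injected'.")
  }
  if (!is.logical(samples$decay_corrected) || anyNA(samples$decay_corrected)) {
    abort("decay_corrected must be TRUE/FALSE, never inferred.")
  }
  samples
}

as_mass_table <- function(organ_masses) {
  if (is.data.frame(organ_masses)) {
    stopifnot(all(c("organ", "mass_g") %in% names(organ_masses)))
    out <- tibble::as_tibble(organ_masses[c("organ", "mass_g")])
  } else {
    out <- tibble::tibble(organ = names(organ_masses),
                          mass_g = as.numeric(organ_masses))
  }
  if (any(out$mass_g <= 0)) {
    abort("organ masses must be positive.", class = "psmadosim_domain_error")
  }
  out
}

#' Remove or apply physical-decay correction on retention values
#'
#' PET retention data are usually decay-corrected to injection time;
#' trapezoidal cumulated-activity integration ([tiac_trapezoid()]) needs the
#' physically decaying (measured) fractions instead. `decay_uncorrect()`
#' multiplies by exp(-lambda t); `decay_correct()` divides.
#'
#' @param points Data frame with columns `time_min` and `value`; if a
#'   `decay_corrected` column is present it is checked and flipped.
#' @param nuclide A [new_nuclide()] record supplying the decay constant.
#' @return The data frame with `value` rescaled and `decay_corrected` flipped.
#' @export
decay_uncorrect <- function(points, nuclide = ga68_decay_data()) {
  points <- tibble::as_tibble(points)
  if ("decay_corrected" %in% names(points) && !all(points$decay_corrected)) {
    abort("points are already non-decay-corrected.")
  }
  points$value <- points$value *
    exp(-nuclide$decay_constant_per_min * points$time_min)
  points$decay_corrected <- FALSE
  points
}

#' @rdname decay_uncorrect
#' @export
decay_correct <- function(points, nuclide = ga68_decay_data()) {
  points <- tibble::as_tibble(points)
  if ("decay_corrected" %in% names(points) && any(points$decay_corrected)) {
    abort("points are already decay-corrected.")
  }
  points$value <- points$value /
    exp(-nuclide$decay_constant_per_min * points$time_min)
  points$decay_corrected <- TRUE
  points
}
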