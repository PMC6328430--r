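#' Read and write the pipeline's CSV interchange formats
#'
#' Plain UTF-8 CSVs with header rows and period decimal separators. Activity
#' samples: `patient_id,organ,time_min,value,value_kind,decay_corrected`.
#' Urine records: `patient_id,void_time_min,voided_fraction`. TIAC tables:
#' `patient_id,organ,tiac_h`. SAF tables:
#' `source,target,particle,energy_MeV,saf_per_kg`. S-value tables:
#' `source,target,gy_per_bq_s`.
#'
#' @param path File path.
#' @return The validated tibble (readers) or `path` invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_activity_samples <- function(path) {
  validate_activity_samples(readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(), organ = readr::col_character(),
      time_min = readr::col_double(), value = readr::col_double(),
      value_kind = readr::col_character(),
      decay_corrected = readr::col_logical())))
}

#' @rdname pipeline_io
#' @param samples A samples tibble.
#' @export
write_activity_samples <- function(samples, path) {
  readr::write_csv(validate_activity_samples(samples), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_urine_records <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         void_time_min = readr::col_double(),
                         voided_fraction = readr::col_double()))
  if (any(x$voided_fraction < 0)) {
    abort("voided fractions must be >= 0.", class = "psmadosim_domain_error")
  }
  x
}

#' @rdname pipeline_io
#' @param urine A urine-records tibble.
#' @export
write_urine_records <- function(urine, path) {
  readr::write_csv(tibble::as_tibble(urine), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_tiac_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    organ = readr::col_character(),
                    tiac_h = readr::col_double()))
}

#' @rdname pipeline_io
#' @param tiacs A TIAC tibble (`patient_id`, `organ`, `tiac_h`).
#' @export
write_tiac_csv <- function(tiacs, path) {
  readr::write_csv(tibble::as_tibble(tiacs), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_saf_csv <- function(path) {
  validate_saf_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname pipeline_io
#' @param safs A SAF tibble.
#' @export
write_saf_csv <- function(safs, path) {
  readr::write_csv(validate_saf_table(safs), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_svalue_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         source = readr::col_character(),
                         target = readr::col_character(),
                         gy_per_bq_s = readr::col_double()))
  if (any(x$gy_per_bq_s < 0)) {
    abort("S-values must be >= 0.", class = "psmadosim_domain_error")
  }
  x
}

#' @rdname pipeline_io
#' @param svalues An S-value tibble.
#' @export
write_svalue_csv <- function(svalues, path) {
  readr::write_csv(tibble::as_tibble(svalues), path)
  invisible(path)
}

#' Export a dose report as CSV or JSON
#'
#' @param report A `dose_report`.
#' @param path Output path; `.json` writes a JSON document with the
#'   per-patient table, the cohort summary, and any effective-dose block,
#'   anything else writes the per-patient CSV.
#' @return `path`, invisibly.
#' @export
write_dose_report <- function(report, path) {
  stopifnot(inherits(report, "dose_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(per_patient = report$per_patient, summary = report$summary,
           effective = report$effective),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    readr::write_csv(report$per_patient, path)
  }
  invisible(path)
}
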