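#' Organ absorbed-dose coefficients from TIACs and S-values
#'
#' The MIRD product: for each patient and target region,
#' `D_T (mGy/MBq) = sum_S TIAC_S(h) x 3.6e9 (Bq.s per MBq.h) x S(T <- S) x 1e3`.
#' Cohort summaries are the per-organ median and range of the per-patient
#' doses.
#'
#' @param tiacs Tibble with columns `patient_id`, `organ`, `tiac_h` (one row
#'   per patient and source region).
#' @param svalues Tibble with columns `source`, `target`, `gy_per_bq_s`
#'   (e.g. from [s_value_table()] or [read_svalue_csv()]).
#' @return A `dose_report`: list with `per_patient` (tibble `patient_id`,
#'   `organ`, `dose_mGy_per_MBq`), `summary` (`organ`, `median_mGy_per_MBq`,
#'   `range_low_mGy_per_MBq`, `range_high_mGy_per_MBq`), and `effective`
#'   (`NULL` until filled by [run_pipeline()] or [effective_dose()]).
#' @examples
#' tiacs <- tibble::tibble(patient_id = "P1", organ = "kidneys", tiac_h = 1)
#' sv <- tibble::tibble(source = "kidneys", target = "kidneys",
#'                      gy_per_bq_s = 1e-13)
#' absorbed_dose(tiacs, sv)$per_patient # 0.36 mGy/MBq
#' @export
absorbed_dose <- function(tiacs, svalues) {
  tiacs <- tibble::as_tibble(tiacs)
  svalues <- tibble::as_tibble(svalues)
  stopifnot(all(c("patient_id", "organ", "tiac_h") %in% names(tiacs)),
            all(c("source", "target", "gy_per_bq_s") %in% names(svalues)))
  if (any(tiacs$tiac_h < 0) || any(svalues$gy_per_bq_s < 0)) {
    abort("TIACs and S-values must be >= 0.", class = "psmadosim_domain_error")
  }
  missing_src <- setdiff(unique(tiacs$organ), unique(svalues$source))
  if (length(missing_src)) {
    abort(paste0("no S-value rows for source region(s): ",
                 paste(missing_src, collapse = ", ")),
          class = "psmadosim_lookup_error")
  }
  per_patient <- tiacs |>
    dplyr::inner_join(svalues, by = c(organ = "source"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$patient_id, organ = .data$target) |>
    dplyr::summarise(
      dose_mGy_per_MBq = sum(.data$tiac_h * .DECAYS_PER_MBQ_H *
                               .data$gy_per_bq_s * 1e3),
      .groups = "drop")
  summary <- per_patient |>
    dplyr::group_by(.data$organ) |>
    dplyr::summarise(
      median_mGy_per_MBq = median(.data$dose_mGy_per_MBq),
      range_low_mGy_per_MBq = min(.data$dose_mGy_per_MBq),
      range_high_mGy_per_MBq = max(.data$dose_mGy_per_MBq),
      .groups = "drop")
  structure(list(per_patient = per_patient, summary = summary,
                 effective = NULL),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %d patient(s), %d target organ(s)\n",
              dplyr::n_distinct(x$per_patient$patient_id), nrow(x$summary)))
  print(dplyr::arrange(x$summary, dplyr::desc(.data$median_mGy_per_MBq)))
  if (!is.null(x$effective)) {
    cat("effective dose:\n")
    print(x$effective)
  }
  invisible(x)
}

#' @export
#' @method tidy dose_report
#' @rdname absorbed_dose
#' @param x A `dose_report`.
#' @param ... Unused.
tidy.dose_report <- function(x, ...) x$per_patient

#' @export
#' @method glance dose_report
#' @rdname absorbed_dose
glance.dose_report <- function(x, ...) {
  top <- x$summary[which.max(x$summary$median_mGy_per_MBq), ]
  tibble::tibble(
    n_patients = dplyr::n_distinct(x$per_patient$patient_id),
    n_organs = nrow(x$summary),
    max_organ = top$organ,
    max_median_mGy_per_MBq = top$median_mGy_per_MBq,
    effective_dose_mSv_per_MBq =
      if (is.null(x$effective)) NA_real_
      else median(x$effective$effective_dose_mSv_per_MBq)
  )
}

#' ICRP tissue weighting factors
#'
#' Tissue weighting factor sets for effective dose. ICRP 103: explicit
#' weights for 14 tissues plus a 0.12 remainder shared by 13 tissues whose
#' mean dose is used. ICRP 60: 12 explicit tissues plus a 0.05 remainder.
#' Weights sum to 1 exactly in both schemes.
#'
#' @param scheme `"ICRP103"` or `"ICRP60"`.
#' @return Tibble `tissue`/`w_T` with attributes `remainder_tissues`
#'   (character vector) and `scheme`.
#' @examples
#' sum(tissue_weights("ICRP103")$w_T) # 1 (0.88 named + 0.12 remainder)
#' @export
tissue_weights <- function(scheme = c("ICRP103", "ICRP60")) {
  scheme <- match.arg(scheme)
  if (scheme == "ICRP103") {
    w <- tibble::tribble(
      ~tissue, ~w_T,
      "gonads", 0.08,
      "red_bone_marrow", 0.12,
      "colon", 0.12,
      "lung", 0.12,
      "stomach", 0.12,
      "breast", 0.12,
      "urinary_bladder", 0.04,
      "oesophagus", 0.04,
      "liver", 0.04,
      "thyroid", 0.04,
      "bone_surface", 0.01,
      "brain", 0.01,
      "salivary_glands", 0.01,
      "skin", 0.01,
      "remainder", 0.12
    )
    rem <- c("adrenals", "extrathoracic_region", "gall_bladder", "heart",
             "kidneys", "lymphatic_nodes", "muscle", "oral_mucosa",
             "pancreas", "prostate", "small_intestine", "spleen", "thymus")
  } else {
    w <- tibble::tribble(
      ~tissue, ~w_T,
      "gonads", 0.20,
      "red_bone_marrow", 0.12,
      "colon", 0.12,
      "lung", 0.12,
      "stomach", 0.12,
      "urinary_bladder", 0.05,
      "breast", 0.05,
      "liver", 0.05,
      "oesophagus", 0.05,
      "thyroid", 0.05,
      "skin", 0.01,
      "bone_surface", 0.01,
      "remainder", 0.05
    )
    rem <- c("adrenals", "brain", "upper_large_intestine", "small_intestine",
             "kidneys", "muscle", "pancreas", "spleen", "thymus")
  }
  stopifnot(abs(sum(w$w_T) - 1) < 1e-12)
  attr(w, "remainder_tissues") <- rem
  attr(w, "scheme") <- scheme
  w
}

# report organ name -> ICRP tissue name; unmapped organs (eye lenses,
# lacrimal glands) carry no tissue weight
.organ_tissue_map <- c(
  kidneys = "kidneys", liver = "liver", lungs = "lung", spleen = "spleen",
  salivary_glands = "salivary_glands", urinary_bladder_wall = "urinary_bladder",
  stomach_wall = "stomach", colon_wall = "colon", esophagus = "oesophagus",
  endosteum = "bone_surface", red_bone_marrow = "red_bone_marrow",
  testes = "gonads", thyroid = "thyroid", skin = "skin", brain = "brain",
  breast = "breast"
)

# reference masses (g) for the mass-weighted remainder variant
.remainder_masses <- c(
  adrenals = 14, extrathoracic_region = 15, gall_bladder = 10, heart = 330,
  kidneys = 310, lymphatic_nodes = 730, muscle = 28000, oral_mucosa = 90,
  pancreas = 140, prostate = 17, small_intestine = 640, spleen = 150,
  thymus = 25, brain = 1450, upper_large_intestine = 210
)

#' Effective dose from organ dose coefficients
#'
#' Tissue-weighted sum `E = sum_T w_T H_T` (radiation weighting factor 1 for
#' photons and electrons, so equivalent dose equals absorbed dose
#' numerically). Report organs are mapped onto ICRP tissue names; tissues
#' absent from the report (breast, brain, the unlisted remainder tissues) are
#' filled per `fill_policy`: by default the median coefficient of the listed
#' non-uptake organs, i.e. excluding the high-uptake/excretion organs whose
#' doses are not representative of the photon background. The remainder
#' tissue dose is the arithmetic mean of its member tissues (ICRP 103
#' convention); for ICRP 60 a mass-weighted variant is available.
#'
#' @param organ_doses A `dose_report` (cohort medians are used), or a tibble
#'   with an `organ` column and a dose column (`median_mGy_per_MBq`,
#'   `dose_mGy_per_MBq`, or `dose`).
#' @param weights A [tissue_weights()] table.
#' @param fill_policy `"median_nonuptake"` or `"value"` (then give
#'   `fill_value`).
#' @param fill_value Coefficient used when `fill_policy = "value"`.
#' @param remainder_rule `"arithmetic"` (default) or `"mass_weighted"`.
#' @param uptake_organs Organs excluded from the fill median.
#' @return One-row tibble: `scheme`, `effective_dose_mSv_per_MBq`,
#'   `fill_mGy_per_MBq`, `remainder_mGy_per_MBq`.
#' @examples
#' effective_dose(psma11_dose_coefficients())
#' @export
effective_dose <- function(organ_doses, weights = tissue_weights("ICRP103"),
                           fill_policy = c("median_nonuptake", "value"),
                           fill_value = NULL,
                           remainder_rule = c("arithmetic", "mass_weighted"),
                           uptake_organs = c("kidneys", "liver", "spleen",
                                             "salivary_glands",
                                             "lacrimal_glands",
                                             "urinary_bladder_wall")) {
  fill_policy <- match.arg(fill_policy)
  remainder_rule <- match.arg(remainder_rule)
  if (inherits(organ_doses, "dose_report")) organ_doses <- organ_doses$summary
  organ_doses <- tibble::as_tibble(organ_doses)
  dose_col <- intersect(c("median_mGy_per_MBq", "dose_mGy_per_MBq", "dose"),
                        names(organ_doses))[1]
  if (is.na(dose_col) || !"organ" %in% names(organ_doses)) {
    abort("organ_doses needs an `organ` column and a dose column.")
  }
  if (abs(sum(weights$w_T) - 1) > 1e-9) {
    abort("tissue weights must sum to 1.", class = "psmadosim_config_error")
  }
  doses <- setNames(organ_doses[[dose_col]], organ_doses$organ)

  fill <- if (fill_policy == "value") {
    if (is.null(fill_value)) abort("fill_value required for fill_policy='value'.")
    fill_value
  } else {
    nonuptake <- doses[!names(doses) %in% uptake_organs]
    if (!length(nonuptake)) abort("no non-uptake organs to take the median of.")
    median(nonuptake)
  }

  tissue_dose <- function(tissue) {
    organ <- names(.organ_tissue_map)[match(tissue, .organ_tissue_map)]
    if (!is.na(organ) && organ %in% names(doses)) return(unname(doses[organ]))
    if (tissue %in% names(doses)) return(unname(doses[tissue]))
    fill
  }

  rem_tissues <- attr(weights, "remainder_tissues")
  rem_doses <- vapply(rem_tissues, tissue_dose, numeric(1))
  rem_dose <- if (remainder_rule == "arithmetic") {
    mean(rem_doses)
  } else {
    m <- .remainder_masses[rem_tissues]
    m[is.na(m)] <- median(.remainder_masses)
    sum(m * rem_doses) / sum(m)
  }

  named <- weights[weights$tissue != "remainder", ]
  e <- sum(named$w_T * vapply(named$tissue, tissue_dose, numeric(1))) +
    weights$w_T[weights$tissue == "remainder"] * rem_dose
  tibble::tibble(
    scheme = attr(weights, "scheme") %||% "custom",
    effective_dose_mSv_per_MBq = e,
    fill_mGy_per_MBq = fill,
    remainder_mGy_per_MBq = rem_dose
  )
}

#' Absolute dose for an administration
#'
#' Multiplies a per-activity coefficient (mGy/MBq or mSv/MBq) by the
#' administered activity, given either directly in MBq or as a weight-based
#' prescription (MBq/kg x kg).
#'
#' @param coefficient Dose coefficient per MBq.
#' @param activity_MBq_per_kg,weight_kg Weight-based prescription.
#' @param administered_MBq Administered activity in MBq (alternative input).
#' @return Absolute dose in the coefficient's numerator unit.
#' @examples
#' dose_for_administration(0.022, activity_MBq_per_kg = 2, weight_kg = 80)
#' dose_for_administration(0.24, administered_MBq = 160)
#' @export
dose_for_administration <- function(coefficient, activity_MBq_per_kg = NULL,
                                    weight_kg = NULL, administered_MBq = NULL) {
  if (is.null(administered_MBq)) {
    if (is.null(activity_MBq_per_kg) || is.null(weight_kg)) {
      abort("give administered_MBq, or activity_MBq_per_kg with weight_kg.")
    }
    if (any(activity_MBq_per_kg < 0) || any(weight_kg <= 0)) {
      abort("prescription inputs must be positive.",
            class = "psmadosim_domain_error")
    }
    administered_MBq <- activity_MBq_per_kg * weight_kg
  }
  if (any(administered_MBq < 0)) {
    abort("administered activity must be >= 0.",
          class = "psmadosim_domain_error")
  }
  coefficient * administered_MBq
}
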