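#' Default ground-truth organ kinetics for the synthetic cohort
#'
#' Uptake-washout kinetics `U(t) = c (exp(-lw t) - exp(-lu t))` per organ,
#' parameterised by the peak fraction of injected activity and the uptake and
#' washout half-times. Peak magnitudes follow the uptakes reported for
#' [68Ga]PSMA-11 (kidneys ~7%, liver ~15%, spleen ~2%, salivary glands
#' ~0.5%); the half-times are package choices of realistic magnitude, not
#' published values.
#'
#' @return Tibble with columns `organ`, `peak_fraction`, `uptake_half_min`,
#'   `washout_half_min`.
#' @export
default_organ_kinetics <- function() {
  tibble::tribble(
    ~organ, ~peak_fraction, ~uptake_half_min, ~washout_half_min,
    "kidneys", 0.07, 5, 300,
    "liver", 0.15, 8, 400,
    "lungs", 0.015, 2, 90,
    "spleen", 0.02, 5, 200,
    "salivary_glands", 0.005, 20, 180,
    "lacrimal_glands", 0.0003, 20, 300
  )
}

#' Specification of a synthetic [68Ga]PSMA-11 cohort
#'
#' Bundles everything the generator needs: cohort size and weights, the
#' 2-MBq/kg administration, organ and blood ground-truth kinetics, the urine
#' excretion model, the sampling schedule (head-to-thigh scans in the first
#' half hour, whole-body scans to 255 min, early image-derived plus venous
#' blood samples, urine voids to 4 h) and the multiplicative measurement
#' noise.
#'
#' @param n_patients Number of patients (default 6).
#' @param weight_range_kg Sampling range for body weight (default 67-90 kg).
#' @param administered_MBq_per_kg Prescription (default 2).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (default 0.02).
#' @param organ_kinetics See [default_organ_kinetics()].
#' @param blood_kinetics Tibble `amplitude`/`half_life_min`; default the
#'   bi-exponential blood clearance 91% at 6.5 min and 9% at 4.4 h.
#' @param urine List with `excreted_fraction` (asymptotic decay-corrected
#'   fraction excreted, default 0.25) and `excretion_half_min` (default 60).
#' @param schedule List with `scan_min`, `blood_min`, `void_min`.
#' @param patient_cv List with lognormal inter-patient coefficients of
#'   variation for kinetic `peak`s and `half_life` times.
#' @param blood_mass_g Reference total blood mass, grams.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 6,
                        weight_range_kg = c(67, 90),
                        administered_MBq_per_kg = 2,
                        noise_cv = 0.02,
                        organ_kinetics = default_organ_kinetics(),
                        blood_kinetics = tibble::tibble(
                          amplitude = c(0.91, 0.09),
                          half_life_min = c(6.5, 264)),
                        urine = list(excreted_fraction = 0.25,
                                     excretion_half_min = 60),
                        schedule = list(
                          scan_min = c(0, 10, 20, 30, 90, 180, 255),
                          blood_min = c(2, 5, 10, 20, 30, 45, 85, 175, 245),
                          void_min = c(60, 120, 180, 240)),
                        patient_cv = list(peak = 0.15, half_life = 0.10),
                        blood_mass_g = 5600) {
  if (noise_cv < 0) abort("noise_cv must be >= 0.",
                          class = "psmadosim_domain_error")
  if (!length(schedule$scan_min)) {
    abort("sampling schedule must not be empty.",
          class = "psmadosim_config_error")
  }
  if (sum(organ_kinetics$peak_fraction) >= 1) {
    abort("organ peak fractions must sum to below 1.",
          class = "psmadosim_domain_error")
  }
  structure(
    list(n_patients = n_patients, weight_range_kg = weight_range_kg,
         administered_MBq_per_kg = administered_MBq_per_kg,
         noise_cv = noise_cv, organ_kinetics = organ_kinetics,
         blood_kinetics = blood_kinetics, urine = urine, schedule = schedule,
         patient_cv = patient_cv, blood_mass_g = blood_mass_g),
    class = "cohort_spec"
  )
}

# retention function for one organ's uptake-washout parameters; c is scaled
# so the curve peaks at peak_fraction
.washin_fun <- function(peak_fraction, uptake_half_min, washout_half_min) {
  lu <- log(2) / uptake_half_min
  lw <- log(2) / washout_half_min
  t_peak <- log(lu / lw) / (lu - lw)
  c0 <- peak_fraction / (exp(-lw * t_peak) - exp(-lu * t_peak))
  list(fn = function(t) c0 * (exp(-lw * t) - exp(-lu * t)),
       amplitude = c0, rate_slow = lw, rate_fast = lu)
}

#' Generate a seeded synthetic patient cohort
#'
#' Evaluates the ground-truth kinetics at the sampling schedule, applies
#' multiplicative Gaussian noise (truncated at zero), converts organ
#' retention to activity concentrations via the reference organ masses, and
#' books urine voids consistently with the cumulative excretion model.
#' Conservation holds exactly in the noiseless ground truth: organ + blood +
#' bladder + voided urine + remainder = 1 at all times.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param organ_masses Mass table used for the concentration conversion.
#' @return A list of class `synthetic_cohort`: `samples` (activity samples,
#'   see [validate_activity_samples()]), `urine` (`patient_id`,
#'   `void_time_min`, `voided_fraction`, not decay-corrected), `truth` (list
#'   with `patients`, `kinetics`, `tiacs`), and `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 2), seed = 1)
#' head(coh$samples)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            organ_masses = reference_organ_masses()) {
  stopifnot(inherits(spec, "cohort_spec"))
  masses <- as_mass_table(organ_masses)
  nuc <- ga68_decay_data()
  lam <- nuc$decay_constant_per_min
  .with_seed(seed, {
    sched <- spec$schedule
    samples <- list(); urine <- list(); kin_rows <- list(); tiac_rows <- list()
    patients <- tibble::tibble(
      patient_id = sprintf("S%d", seq_len(spec$n_patients)),
      weight_kg = runif(spec$n_patients, spec$weight_range_kg[1],
                        spec$weight_range_kg[2]))
    patients$administered_MBq <-
      spec$administered_MBq_per_kg * patients$weight_kg

    noisy <- function(x) {
      if (spec$noise_cv == 0) return(x)
      pmax(x * (1 + rnorm(length(x), 0, spec$noise_cv)), 0)
    }

    for (p in seq_len(spec$n_patients)) {
      pid <- patients$patient_id[p]
      a0 <- patients$administered_MBq[p] * 1e6

      ok <- spec$organ_kinetics
      ok$peak_fraction <- ok$peak_fraction *
        exp(rnorm(nrow(ok), 0, spec$patient_cv$peak))
      ok$uptake_half_min <- ok$uptake_half_min *
        exp(rnorm(nrow(ok), 0, spec$patient_cv$half_life))
      ok$washout_half_min <- ok$washout_half_min *
        exp(rnorm(nrow(ok), 0, spec$patient_cv$half_life))

      organ_fns <- purrr::pmap(ok, function(organ, peak_fraction,
                                            uptake_half_min,
                                            washout_half_min) {
        .washin_fun(peak_fraction, uptake_half_min, washout_half_min)
      })
      names(organ_fns) <- ok$organ

      bk <- spec$blood_kinetics
      blood_fn <- function(t) {
        rowSums(vapply(seq_len(nrow(bk)), function(i)
          bk$amplitude[i] * exp(-log(2) / bk$half_life_min[i] * t),
          numeric(length(t))))
      }
      uf <- spec$urine$excreted_fraction
      le <- log(2) / spec$urine$excretion_half_min
      urine_fn <- function(t) uf * (1 - exp(-le * t))

      # organ concentration samples at scan times
      for (org in ok$organ) {
        m_g <- masses$mass_g[masses$organ == org]
        u <- organ_fns[[org]]$fn(sched$scan_min)
        samples[[length(samples) + 1]] <- tibble::tibble(
          patient_id = pid, organ = org, time_min = sched$scan_min,
          value = noisy(u * a0 / m_g),
          value_kind = "concentration_Bq_per_mL", decay_corrected = TRUE)
      }
      # blood concentration samples
      samples[[length(samples) + 1]] <- tibble::tibble(
        patient_id = pid, organ = "blood", time_min = sched$blood_min,
        value = noisy(blood_fn(sched$blood_min) * a0 / spec$blood_mass_g),
        value_kind = "concentration_Bq_per_mL", decay_corrected = TRUE)
      # bladder content (fraction of injected activity) at scan times
      voids <- sched$void_min
      last_void <- vapply(sched$scan_min, function(t) {
        prev <- voids[voids <= t]
        if (length(prev)) max(prev) else 0
      }, numeric(1))
      content <- urine_fn(sched$scan_min) - urine_fn(last_void)
      samples[[length(samples) + 1]] <- tibble::tibble(
        patient_id = pid, organ = "urinary_bladder_contents",
        time_min = sched$scan_min, value = noisy(content),
        value_kind = "fraction_injected", decay_corrected = TRUE)
      # voided urine: measured (physically decayed) increments
      inc_dc <- diff(c(0, urine_fn(voids)))
      urine[[length(urine) + 1]] <- tibble::tibble(
        patient_id = pid, void_time_min = voids,
        voided_fraction = noisy(inc_dc * exp(-lam * voids)))

      # ground-truth TIACs (analytic where closed forms exist)
      organ_tiacs <- vapply(ok$organ, function(org) {
        f <- organ_fns[[org]]
        f$amplitude * (1 / (f$rate_slow + lam) - 1 / (f$rate_fast + lam)) / 60
      }, numeric(1))
      blood_tiac <- sum(bk$amplitude /
                          (log(2) / bk$half_life_min + lam)) / 60
      # dosimetry voiding convention (3.5/7 h) applied to the cumulative
      # urine-plus-bladder inflow, for both the bladder and the total body
      conv_min <- c(3.5, 7) * 60
      bladder_tiac <- bladder_cumulated_activity(
        function(t) urine_fn(t), void_times_h = conv_min / 60, nuclide = nuc,
        dt_min = 0.1)
      inc_conv <- diff(c(0, urine_fn(conv_min)))
      total_tiac <- (1 / lam - sum(inc_conv * exp(-lam * conv_min)) / lam) / 60
      remainder_tiac <- total_tiac - sum(organ_tiacs) - blood_tiac -
        bladder_tiac
      tiac_rows[[length(tiac_rows) + 1]] <- tibble::tibble(
        patient_id = pid,
        organ = c(ok$organ, "blood", "urinary_bladder_contents", "remainder"),
        tiac_h = unname(c(organ_tiacs, blood_tiac, bladder_tiac,
                          remainder_tiac)))
      kin_rows[[length(kin_rows) + 1]] <- dplyr::mutate(ok, patient_id = pid,
                                                        .before = 1)
    }
    structure(
      list(samples = dplyr::bind_rows(samples),
           urine = dplyr::bind_rows(urine),
           truth = list(patients = patients,
                        kinetics = dplyr::bind_rows(kin_rows),
                        tiacs = dplyr::bind_rows(tiac_rows)),
           spec = spec),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d samples, noise CV %.3g\n",
              nrow(x$truth$patients), nrow(x$samples), x$spec$noise_cv))
  print(x$truth$patients)
  invisible(x)
}
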