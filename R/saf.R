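#' Validate a specific-absorbed-fraction (SAF) table
#'
#' A SAF table maps (source region, target region, particle kind, energy) to
#' the absorbed fraction per unit target mass in 1/kg. Users with access to
#' full phantom SAF compilations can load them with [read_saf_csv()]; the
#' package otherwise provides [simplified_saf()].
#'
#' @param safs Data frame with columns `source`, `target`, `particle`
#'   ("electron"/"photon"), `energy_MeV`, `saf_per_kg`.
#' @return The table as a tibble; errors on schema violations, negative SAFs,
#'   or a region lacking positive self-irradiation SAFs.
#' @export
validate_saf_table <- function(safs) {
  safs <- tibble::as_tibble(safs)
  req <- c("source", "target", "particle", "energy_MeV", "saf_per_kg")
  miss <- setdiff(req, names(safs))
  if (length(miss)) {
    abort(paste0("SAF table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(safs$saf_per_kg < 0)) {
    abort("SAFs must be >= 0.", class = "psmadosim_domain_error")
  }
  self <- safs[safs$source == safs$target, ]
  regions <- unique(c(safs$source, safs$target))
  no_self <- setdiff(regions, self$source[self$saf_per_kg > 0])
  if (length(no_self)) {
    abort(paste0("regions without positive self-irradiation SAF: ",
                 paste(no_self, collapse = ", ")))
  }
  safs
}

#' Simplified SAF table for a positron emitter
#'
#' A self-contained stand-in for full phantom SAF compilations, built from
#' the package's own transport models: electron (positron) self-SAFs are
#' `phi_e / m` with the absorbed fraction from the sphere Monte Carlo run on
#' a sphere of each organ's mass; photon self-SAFs are `phi_gamma / m` from
#' the single-interaction mu_en chord quadrature; photon cross-fire between
#' distinct organs uses a uniform whole-body bath (every target receives the
#' total-body absorbed fraction per total-body mass); electron cross-fire is
#' zero (explicit zero rows, so lookups stay strict). Adequate for
#' photon/positron emitters in non-walled organs; bladder-wall dose from
#' content requires a user-supplied content-to-wall S-value.
#'
#' @param masses Organ mass table (data frame `organ`/`mass_g` or named
#'   vector); default [reference_organ_masses()].
#' @param nuclide Decay data (supplies the positron spectrum and photon
#'   lines).
#' @param n_histories Histories per organ for the electron Monte Carlo.
#' @param seed Seed for the electron Monte Carlo (fixed default keeps the
#'   table deterministic).
#' @param total_body_organ Name of the region used for the bath mass.
#' @return A SAF tibble (see [validate_saf_table()]).
#' @export
simplified_saf <- function(masses = reference_organ_masses(),
                           nuclide = ga68_decay_data(),
                           n_histories = 2e4, seed = 1,
                           total_body_organ = "total_body") {
  masses <- as_mass_table(masses)
  m_tb_g <- if (total_body_organ %in% masses$organ) {
    masses$mass_g[masses$organ == total_body_organ]
  } else {
    sum(masses$mass_g)
  }
  em <- nuclide$emissions
  e_mean <- em$energy_MeV[em$kind == "electron"][1]
  photon_E <- unique(em$energy_MeV[em$kind == "photon"])

  organs <- masses$organ
  rows <- vector("list", 0)
  phi_tb <- vapply(photon_E, function(E)
    .sphere_photon_af(sphere_spec(m_tb_g)$radius_cm, E), numeric(1))

  for (i in seq_along(organs)) {
    org <- organs[i]
    m_g <- masses$mass_g[i]
    sph <- sphere_spec(m_g)
    mc <- sphere_self_dose(sph, nuclide, n_histories = n_histories,
                           seed = seed + i)
    rows[[length(rows) + 1]] <- tibble::tibble(
      source = org, target = org, particle = "electron",
      energy_MeV = e_mean, saf_per_kg = mc$electron_af / (m_g / 1000))
    rows[[length(rows) + 1]] <- tibble::tibble(
      source = org, target = org, particle = "photon",
      energy_MeV = photon_E,
      saf_per_kg = vapply(photon_E, function(E)
        .sphere_photon_af(sph$radius_cm, E), numeric(1)) / (m_g / 1000))
  }
  # cross-fire: uniform whole-body photon bath, zero electron rows
  cross <- tidyr::expand_grid(source = organs, target = organs)
  cross <- cross[cross$source != cross$target, ]
  if (nrow(cross)) {
    rows[[length(rows) + 1]] <- tidyr::expand_grid(
      cross, tibble::tibble(energy_MeV = photon_E,
                            bath = phi_tb / (m_tb_g / 1000))) |>
      dplyr::mutate(particle = "photon", saf_per_kg = .data$bath) |>
      dplyr::select("source", "target", "particle", "energy_MeV", "saf_per_kg")
    rows[[length(rows) + 1]] <- dplyr::mutate(
      cross, particle = "electron", energy_MeV = e_mean, saf_per_kg = 0)
  }
  validate_saf_table(dplyr::bind_rows(rows))
}

#' S-value (Gy per Bq.s) for a source-target region pair
#'
#' The MIRD-schema dose factor: the emission-spectrum-weighted sum of
#' specific absorbed fractions,
#' `S = sum_i y_i E_i SAF(target <- source; E_i, kind_i)` with energies
#' converted to joules. SAF energies are matched by log-log interpolation
#' within each (source, target, particle) group (nearest value outside the
#' tabulated range, or for single-entry groups).
#'
#' @param source,target Region names.
#' @param nuclide Decay data with the emissions table.
#' @param safs SAF table (see [validate_saf_table()]).
#' @return S-value in Gy per Bq.s.
#' @examples
#' safs <- tibble::tibble(source = "organ", target = "organ",
#'                        particle = "electron", energy_MeV = 1,
#'                        saf_per_kg = 1)
#' nuc <- new_nuclide("E1", 60, tibble::tibble(kind = "electron", yield = 1,
#'                                             energy_MeV = 1))
#' s_value("organ", "organ", nuc, safs) # 1.602e-13
#' @export
s_value <- function(source, target, nuclide, safs) {
  safs <- tibble::as_tibble(safs)
  pair <- safs[safs$source == source & safs$target == target, ]
  if (nrow(pair) == 0) {
    abort(sprintf("no SAF entries for pair (%s -> %s).", source, target),
          class = "psmadosim_lookup_error")
  }
  em <- nuclide$emissions
  total <- 0
  for (i in seq_len(nrow(em))) {
    sub <- pair[pair$particle == em$kind[i], ]
    if (nrow(sub) == 0) {
      abort(sprintf("no %s SAF for pair (%s -> %s).",
                    em$kind[i], source, target),
            class = "psmadosim_lookup_error")
    }
    saf <- .interp_saf(sub, em$energy_MeV[i])
    total <- total + em$yield[i] * em$energy_MeV[i] * .MEV_TO_J * saf
  }
  total
}

.interp_saf <- function(sub, energy_MeV) {
  if (nrow(sub) == 1) return(sub$saf_per_kg)
  sub <- sub[order(sub$energy_MeV), ]
  pos <- sub$saf_per_kg > 0
  if (all(pos)) {
    exp(approx(log(sub$energy_MeV), log(sub$saf_per_kg),
               xout = log(energy_MeV), rule = 2)$y)
  } else {
    approx(sub$energy_MeV, sub$saf_per_kg, xout = energy_MeV, rule = 2)$y
  }
}

#' Build a full S-value table from a SAF table
#'
#' @param nuclide Decay data.
#' @param safs SAF table.
#' @return Tibble with columns `source`, `target`, `gy_per_bq_s`, one row per
#'   (source, target) pair present in `safs`.
#' @export
s_value_table <- function(nuclide = ga68_decay_data(), safs = simplified_saf()) {
  safs <- validate_saf_table(safs)
  pairs <- dplyr::distinct(safs, .data$source, .data$target)
  pairs$gy_per_bq_s <- purrr::map2_dbl(
    pairs$source, pairs$target,
    function(s, t) s_value(s, t, nuclide, safs))
  pairs
}
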