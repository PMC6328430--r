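#' Physical decay constant from a half-life
#'
#' @param half_life_min Half-life in minutes. Must be positive.
#' @return Decay constant in 1/min (`ln(2) / half_life_min`).
#' @examples
#' decay_constant(67.71) # ~0.0102 min^-1 for 68Ga
#' @export
decay_constant <- function(half_life_min) {
  if (!is.numeric(half_life_min) || any(!is.finite(half_life_min)) ||
      any(half_life_min <= 0)) {
    abort("`half_life_min` must be a positive, finite number.",
          class = "psmadosim_domain_error")
  }
  log(2) / half_life_min
}

#' Bundled gallium-68 decay data
#'
#' All decay physics used by the pipeline lives in this record: the 67.71-min
#' half-life, the positron branch (yield 0.889, mean energy 0.836 MeV,
#' beta-spectrum endpoint 1.899 MeV), the two annihilation photons per positron
#' (0.511 MeV, yield 1.778 per decay), the 1.077-MeV gamma line (yield 0.0322),
#' and the mean/maximum positron ranges in soft tissue (3.5 / 9.2 mm). The
#' electron-capture branch (11%) emits no particles tracked here.
#'
#' The continuum of positron energies is represented in the emissions table by
#' its mean energy; the Monte Carlo routines sample the full beta spectrum from
#' the stored endpoint instead (see [sphere_self_dose()]).
#'
#' @return An object of class `nuclide`: a list with fields `name`,
#'   `half_life_min`, `decay_constant_per_min`, `emissions` (a tibble with
#'   columns `kind`, `yield`, `energy_MeV`), `mean_electron_energy_per_decay_MeV`,
#'   `mean_photon_energy_per_decay_MeV`, `mean_positron_range_mm`,
#'   `max_positron_range_mm`, and `beta_endpoint_MeV`.
#' @examples
#' ga68 <- ga68_decay_data()
#' ga68$half_life_min
#' @export
ga68_decay_data <- function() {
  emissions <- tibble::tibble(
    kind = c("electron", "photon", "photon"),
    yield = c(0.889, 1.778, 0.0322),
    energy_MeV = c(0.836, 0.510999, 1.0772)
  )
  new_nuclide(
    name = "Ga-68",
    half_life_min = 67.71,
    emissions = emissions,
    mean_positron_range_mm = 3.5,
    max_positron_range_mm = 9.2,
    beta_endpoint_MeV = 1.899
  )
}

#' Construct a nuclide decay record
#'
#' @param name Nuclide label.
#' @param half_life_min Physical half-life in minutes.
#' @param emissions Tibble with columns `kind` ("electron" or "photon"),
#'   `yield` (per decay) and `energy_MeV` (mean energy for continua).
#' @param mean_positron_range_mm,max_positron_range_mm Positron ranges in
#'   unit-density tissue, millimetres.
#' @param beta_endpoint_MeV Endpoint of the positron spectrum, MeV (used by the
#'   Monte Carlo sampler); `NA` for non-positron emitters.
#' @return A validated object of class `nuclide`.
#' @export
new_nuclide <- function(name, half_life_min, emissions,
                        mean_positron_range_mm = NA_real_,
                        max_positron_range_mm = NA_real_,
                        beta_endpoint_MeV = NA_real_) {
  emissions <- tibble::as_tibble(emissions)
  x <- structure(
    list(
      name = name,
      half_life_min = half_life_min,
      decay_constant_per_min = decay_constant(half_life_min),
      emissions = emissions,
      mean_electron_energy_per_decay_MeV =
        sum(emissions$yield[emissions$kind == "electron"] *
              emissions$energy_MeV[emissions$kind == "electron"]),
      mean_photon_energy_per_decay_MeV =
        sum(emissions$yield[emissions$kind == "photon"] *
              emissions$energy_MeV[emissions$kind == "photon"]),
      mean_positron_range_mm = mean_positron_range_mm,
      max_positron_range_mm = max_positron_range_mm,
      beta_endpoint_MeV = beta_endpoint_MeV
    ),
    class = "nuclide"
  )
  validate_nuclide(x)
}

#' Validate a nuclide record
#'
#' Checks the invariants: decay constant times half-life equals ln 2, all
#' yields nonnegative, all energies positive, and mean positron range below
#' the maximum.
#'
#' @param x A `nuclide` object.
#' @return `x`, invisibly valid; errors otherwise.
#' @export
validate_nuclide <- function(x) {
  stopifnot(inherits(x, "nuclide"))
  if (abs(x$decay_constant_per_min * x$half_life_min / log(2) - 1) > 1e-12) {
    abort("decay_constant_per_min * half_life_min must equal ln 2.",
          class = "psmadosim_domain_error")
  }
  em <- x$emissions
  if (!all(c("kind", "yield", "energy_MeV") %in% names(em))) {
    abort("emissions must have columns kind, yield, energy_MeV.")
  }
  if (!all(em$kind %in% c("electron", "photon"))) {
    abort("emission kind must be 'electron' or 'photon'.")
  }
  if (any(em$yield < 0) || any(em$energy_MeV <= 0)) {
    abort("yields must be >= 0 and energies > 0.",
          class = "psmadosim_domain_error")
  }
  if (is.finite(x$mean_positron_range_mm) && is.finite(x$max_positron_range_mm) &&
      x$mean_positron_range_mm >= x$max_positron_range_mm) {
    abort("mean positron range must be below the maximum range.",
          class = "psmadosim_domain_error")
  }
  x
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s  (t1/2 = %.4g min, lambda = %.5g /min)\n",
              x$name, x$half_life_min, x$decay_constant_per_min))
  cat(sprintf("  mean E per decay: %.3f MeV (electron), %.3f MeV (photon)\n",
              x$mean_electron_energy_per_decay_MeV,
              x$mean_photon_energy_per_decay_MeV))
  print(x$emissions)
  invisible(x)
}

#' Export or import nuclide decay data as JSON
#'
#' @param x A `nuclide` object.
#' @param path File path; if `NULL`, `nuclide_to_json()` returns a JSON string.
#' @return `nuclide_to_json()`: the path or a JSON string.
#'   `nuclide_from_json()`: a `nuclide` object.
#' @export
nuclide_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "nuclide"))
  doc <- list(
    name = x$name,
    half_life_min = x$half_life_min,
    emissions = x$emissions,
    mean_positron_range_mm = x$mean_positron_range_mm,
    max_positron_range_mm = x$max_positron_range_mm,
    beta_endpoint_MeV = x$beta_endpoint_MeV
  )
  if (is.null(path)) {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname nuclide_to_json
#' @param json A file path or JSON string produced by [nuclide_to_json()].
#' @export
nuclide_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  new_nuclide(
    name = doc$name,
    half_life_min = doc$half_life_min,
    emissions = tibble::as_tibble(doc$emissions),
    mean_positron_range_mm = doc$mean_positron_range_mm %||% NA_real_,
    max_positron_range_mm = doc$max_positron_range_mm %||% NA_real_,
    beta_endpoint_MeV = doc$beta_endpoint_MeV %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
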