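#' Specify a unit-density sphere
#'
#' @param mass_g Sphere mass in grams.
#' @param density_g_per_cm3 Density, default 1 (soft tissue / water).
#' @return An object of class `sphere_spec` with the derived `radius_cm`.
#' @examples
#' sphere_spec(0.7) # a lacrimal gland
#' @export
sphere_spec <- function(mass_g, density_g_per_cm3 = 1) {
  if (!is.numeric(mass_g) || mass_g <= 0 || density_g_per_cm3 <= 0) {
    abort("sphere mass and density must be positive.",
          class = "psmadosim_domain_error")
  }
  structure(
    list(mass_g = mass_g, density_g_per_cm3 = density_g_per_cm3,
         radius_cm = (3 * mass_g / (4 * pi * density_g_per_cm3))^(1 / 3)),
    class = "sphere_spec"
  )
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf("<sphere_spec> %.4g g, rho = %.3g g/cm3, radius = %.4g cm\n",
              x$mass_g, x$density_g_per_cm3, x$radius_cm))
  invisible(x)
}

# isotropic unit vectors, n x 3
.iso_dirs <- function(n) {
  u <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(s * cos(phi), s * sin(phi), u)
}

# distance from an interior point at radius r to the sphere surface along a
# direction making cos-angle u with the outward radius vector
.chord_to_surface <- function(R, r, u) {
  -r * u + sqrt(pmax(R^2 - r^2 * (1 - u^2), 0))
}

#' Monte Carlo self-dose of a unit-density sphere
#'
#' Absorbed dose per decay for activity uniformly distributed in a sphere.
#' Decay sites are uniform in the volume with isotropic emission; positrons
#' are transported as straight CSDA tracks (kinetic energy sampled from the
#' beta spectrum, residual range converted back to energy where the track
#' crosses the surface, track length capped at the nuclide's maximum positron
#' range); annihilation photons are emitted back-to-back at the positron
#' endpoint (clamped to the surface for escaping positrons) and the gamma
#' line at the decay site, all depositing via a single-interaction
#' energy-absorption (mu_en) model along the chord. Emission yields enter as
#' per-history weights.
#'
#' @param sphere A [sphere_spec()].
#' @param nuclide Decay data; needs a beta endpoint for positron emitters.
#' @param n_histories Number of decay histories (>= 1e4).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   tallies.
#' @return An `af_result`: list with `electron_af`, `photon_af`,
#'   `dose_per_decay_Gy`, `photon_share` (fraction of the dose carried by the
#'   511-keV annihilation photons), `mc_uncertainty` (relative standard
#'   error), `converged` (RSE <= 2%), plus emitted/deposited energy
#'   bookkeeping (`emitted_MeV_per_decay`, `deposited_MeV_per_decay`,
#'   `max_history_excess_MeV`, the largest per-history deposited-minus-emitted
#'   difference, nonpositive when energy is conserved).
#' @examples
#' \donttest{
#' res <- sphere_self_dose(sphere_spec(0.7), n_histories = 1e5, seed = 1)
#' res$dose_per_decay_Gy
#' }
#' @export
sphere_self_dose <- function(sphere, nuclide = ga68_decay_data(),
                             n_histories = 1e5, seed = NULL) {
  stopifnot(inherits(sphere, "sphere_spec"))
  if (n_histories < 1e4) {
    abort("n_histories must be at least 1e4.", class = "psmadosim_domain_error")
  }
  .with_seed(seed, {
    R <- sphere$radius_cm
    mass_kg <- sphere$mass_g / 1000
    cap_cm <- nuclide$max_positron_range_mm / 10
    em <- nuclide$emissions
    y_beta <- sum(em$yield[em$kind == "electron"])
    gammas <- em[em$kind == "photon" & abs(em$energy_MeV - 0.511) > 0.01, ]

    n <- as.integer(n_histories)
    dep_e <- dep_511 <- dep_g <- numeric(n)
    emit_e <- emit_511 <- emit_g <- numeric(n)
    chunk <- 2e5L
    done <- 0L
    while (done < n) {
      m <- min(chunk, n - done)
      idx <- done + seq_len(m)
      r <- R * runif(m)^(1 / 3)
      # positron branch (weight y_beta)
      u <- runif(m, -1, 1)
      d_surf <- .chord_to_surface(R, r, u)
      E <- .sample_beta_energy(m, nuclide$beta_endpoint_MeV)
      rng <- pmin(.electron_range_cm(E), cap_cm)
      escapes <- d_surf < rng
      E_res <- ifelse(escapes,
                      .electron_energy_from_range(.electron_range_cm(E) - d_surf),
                      0)
      dep_e[idx] <- y_beta * (E - E_res)
      emit_e[idx] <- y_beta * E
      # annihilation point: endpoint of the track, clamped to the surface
      s_end <- pmin(rng, d_surf)
      r_ann <- sqrt(pmax(r^2 + s_end^2 + 2 * r * s_end * u, 0))
      r_ann <- pmin(r_ann, R)
      mu511 <- .muen_water_at(0.511)
      dep_pair <- numeric(m)
      for (k in 1:2) {
        u2 <- runif(m, -1, 1)
        chord <- .chord_to_surface(R, r_ann, u2)
        dep_pair <- dep_pair + 0.511 * (1 - exp(-mu511 * chord))
      }
      dep_511[idx] <- y_beta * dep_pair
      emit_511[idx] <- y_beta * 2 * 0.511
      # discrete gamma lines from the decay site
      if (nrow(gammas)) {
        dg <- eg <- numeric(m)
        for (j in seq_len(nrow(gammas))) {
          u3 <- runif(m, -1, 1)
          chord <- .chord_to_surface(R, r, u3)
          mug <- .muen_water_at(gammas$energy_MeV[j])
          dg <- dg + gammas$yield[j] * gammas$energy_MeV[j] *
            (1 - exp(-mug * chord))
          eg <- eg + gammas$yield[j] * gammas$energy_MeV[j]
        }
        dep_g[idx] <- dg
        emit_g[idx] <- eg
      }
      done <- done + m
    }
    dep_tot <- dep_e + dep_511 + dep_g
    emit_tot <- emit_e + emit_511 + emit_g
    dose <- mean(dep_tot) * .MEV_TO_J / mass_kg
    rse <- sd(dep_tot) / sqrt(n) / mean(dep_tot)
    new_af_result(
      electron_af = sum(dep_e) / sum(emit_e),
      photon_af = sum(dep_511 + dep_g) / sum(emit_511 + emit_g),
      dose_per_decay_Gy = dose,
      photon_share = sum(dep_511) / sum(dep_tot),
      mc_uncertainty = rse,
      emitted_MeV_per_decay = mean(emit_tot),
      deposited_MeV_per_decay = mean(dep_tot),
      max_history_excess_MeV = max(dep_tot - emit_tot),
      n_histories = n, seed = seed
    )
  })
}

new_af_result <- function(...) {
  x <- list(...)
  x$converged <- is.finite(x$mc_uncertainty) && x$mc_uncertainty <= 0.02
  stopifnot(x$electron_af >= 0, x$electron_af <= 1 + 1e-12,
            x$photon_af >= 0, x$photon_af <= 1 + 1e-12,
            x$dose_per_decay_Gy >= 0,
            x$photon_share >= 0, x$photon_share <= 1 + 1e-12)
  structure(x, class = "af_result")
}

#' @export
print.af_result <- function(x, ...) {
  cat(sprintf(paste0("<af_result> dose/decay = %.4g Gy (%.4g mGy/MBq.h), ",
                     "AF(e) = %.3f, AF(photon) = %.4f\n"),
              x$dose_per_decay_Gy,
              per_decay_to_per_mbq_h(x$dose_per_decay_Gy),
              x$electron_af, x$photon_af))
  cat(sprintf("  511-keV share %.3f, MC RSE %.3g%s, n = %g\n",
              x$photon_share, x$mc_uncertainty,
              if (!x$converged) " (not converged)" else "", x$n_histories))
  invisible(x)
}

#' @export
#' @method tidy af_result
#' @rdname sphere_self_dose
#' @param x An `af_result`.
#' @param ... Unused.
tidy.af_result <- function(x, ...) {
  tibble::tibble(
    electron_af = x$electron_af, photon_af = x$photon_af,
    dose_per_decay_Gy = x$dose_per_decay_Gy,
    dose_rate_mGy_per_MBq_h = per_decay_to_per_mbq_h(x$dose_per_decay_Gy),
    photon_share = x$photon_share, mc_uncertainty = x$mc_uncertainty,
    converged = x$converged, n_histories = x$n_histories
  )
}

#' Convert a per-decay dose factor to a dose rate per cumulated activity
#'
#' One MBq.h of time-integrated activity is 3.6e9 decays, so
#' `Gy/decay * 3.6e9 * 1000` gives mGy per MBq.h.
#'
#' @param dose_per_decay_Gy Dose factor in Gy per decay (>= 0).
#' @return Dose rate in mGy/(MBq.h).
#' @examples
#' per_decay_to_per_mbq_h(1.19e-10) # ~428 mGy/(MBq.h)
#' @export
per_decay_to_per_mbq_h <- function(dose_per_decay_Gy) {
  if (any(dose_per_decay_Gy < 0)) {
    abort("dose per decay must be >= 0.", class = "psmadosim_domain_error")
  }
  dose_per_decay_Gy * .DECAYS_PER_MBQ_H * 1e3
}

#' Lacrimal-gland absorbed-dose coefficient from the pair TIAC
#'
#' The bundled TIAC for the lacrimal glands is the two-gland total; each
#' 0.7-g gland receives half of it, times the sphere-model self-dose rate.
#'
#' @param pair_tiac_h Two-gland total TIAC in hours.
#' @param dose_rate_mGy_per_MBq_h Self-dose rate of a single gland from the
#'   sphere model, mGy/(MBq.h).
#' @return Absorbed-dose coefficient in mGy/MBq.
#' @examples
#' lacrimal_dose_coefficient(0.00053, 428) # ~0.11 mGy/MBq
#' @export
lacrimal_dose_coefficient <- function(pair_tiac_h, dose_rate_mGy_per_MBq_h) {
  if (any(pair_tiac_h < 0)) {
    abort("TIAC must be >= 0.", class = "psmadosim_domain_error")
  }
  (pair_tiac_h / 2) * dose_rate_mGy_per_MBq_h
}

#' Gland-to-lens geometry
#'
#' Two unit-density spheres in a water medium: the lacrimal gland (source)
#' and the eye lens (target). The default 24-mm centre separation is the
#' approximate eyeball diameter; the default lens is a 0.2-g sphere.
#'
#' @param gland,lens [sphere_spec()] objects.
#' @param center_separation_mm Centre-to-centre distance in mm; must exceed
#'   the sum of the radii.
#' @return An object of class `gland_lens_geometry`.
#' @export
gland_lens_geometry <- function(gland = sphere_spec(0.7),
                                lens = sphere_spec(0.2),
                                center_separation_mm = 24) {
  sep_cm <- center_separation_mm / 10
  if (sep_cm <= gland$radius_cm + lens$radius_cm) {
    abort("spheres overlap: separation must exceed the sum of the radii.",
          class = "psmadosim_geometry_error")
  }
  structure(list(gland = gland, lens = lens,
                 center_separation_mm = center_separation_mm),
            class = "gland_lens_geometry")
}

#' Monte Carlo lens dose from activity in the lacrimal gland
#'
#' Same transport model as [sphere_self_dose()], but tallying the energy
#' deposited in the lens sphere: positron straight tracks are intersected
#' with the lens (their contribution is exactly zero whenever the surface gap
#' exceeds the maximum positron range), annihilation photons start at the
#' positron endpoint and the gamma line at the decay site, attenuating with
#' mu_en to the lens entry and depositing along the lens chord.
#'
#' @param geom A [gland_lens_geometry()].
#' @inheritParams sphere_self_dose
#' @return An `af_result`; `dose_per_decay_Gy` is the lens dose per decay in
#'   the gland and `photon_share` the 511-keV fraction of it.
#' @export
lens_dose_from_gland <- function(geom, nuclide = ga68_decay_data(),
                                 n_histories = 2e5, seed = NULL) {
  stopifnot(inherits(geom, "gland_lens_geometry"))
  if (n_histories < 1e4) {
    abort("n_histories must be at least 1e4.", class = "psmadosim_domain_error")
  }
  .with_seed(seed, {
    Rg <- geom$gland$radius_cm
    Rl <- geom$lens$radius_cm
    sep <- geom$center_separation_mm / 10
    mass_kg <- geom$lens$mass_g / 1000
    cap_cm <- nuclide$max_positron_range_mm / 10
    em <- nuclide$emissions
    y_beta <- sum(em$yield[em$kind == "electron"])
    gammas <- em[em$kind == "photon" & abs(em$energy_MeV - 0.511) > 0.01, ]
    lens_c <- c(sep, 0, 0)

    # segment [t1,t2] (>=0) where the ray p + t w crosses the lens sphere
    ray_lens <- function(p, w) {
      q <- sweep(p, 2, lens_c)
      b <- rowSums(q * w)
      cc <- rowSums(q^2) - Rl^2
      disc <- b^2 - cc
      hit <- disc > 0
      sq <- sqrt(pmax(disc, 0))
      t1 <- pmax(-b - sq, 0)
      t2 <- -b + sq
      hit <- hit & t2 > 0
      list(hit = hit, t1 = t1, t2 = t2)
    }

    n <- as.integer(n_histories)
    dep_e <- dep_511 <- dep_g <- numeric(n)
    emit_e <- emit_511 <- emit_g <- numeric(n)
    mu511 <- .muen_water_at(0.511)
    chunk <- 2e5L
    done <- 0L
    while (done < n) {
      m <- min(chunk, n - done)
      idx <- done + seq_len(m)
      p <- .iso_dirs(m) * (Rg * runif(m)^(1 / 3))
      # positron track
      w <- .iso_dirs(m)
      E <- .sample_beta_energy(m, nuclide$beta_endpoint_MeV)
      full_rng <- .electron_range_cm(E)
      trk <- pmin(full_rng, cap_cm)
      hit <- ray_lens(p, w)
      s_in <- pmin(pmax(hit$t1, 0), trk)
      s_out <- pmin(hit$t2, trk)
      seg <- hit$hit & s_out > s_in
      E_in <- .electron_energy_from_range(full_rng - s_in)
      E_out <- .electron_energy_from_range(full_rng - s_out)
      dep_e[idx] <- ifelse(seg, y_beta * (E_in - E_out), 0)
      emit_e[idx] <- y_beta * E
      # annihilation pair from the track endpoint
      pe <- p + w * trk
      w2 <- .iso_dirs(m)
      dp <- numeric(m)
      for (sgn in c(1, -1)) {
        h <- ray_lens(pe, sgn * w2)
        add <- 0.511 * exp(-mu511 * h$t1) * (1 - exp(-mu511 * (h$t2 - h$t1)))
        dp <- dp + ifelse(h$hit, add, 0)
      }
      dep_511[idx] <- y_beta * dp
      emit_511[idx] <- y_beta * 2 * 0.511
      # gamma lines from the decay site
      if (nrow(gammas)) {
        dg <- eg <- numeric(m)
        for (j in seq_len(nrow(gammas))) {
          w3 <- .iso_dirs(m)
          h <- ray_lens(p, w3)
          mug <- .muen_water_at(gammas$energy_MeV[j])
          add <- gammas$yield[j] * gammas$energy_MeV[j] *
            exp(-mug * h$t1) * (1 - exp(-mug * (h$t2 - h$t1)))
          dg <- dg + ifelse(h$hit, add, 0)
          eg <- eg + gammas$yield[j] * gammas$energy_MeV[j]
        }
        dep_g[idx] <- dg
        emit_g[idx] <- eg
      }
      done <- done + m
    }
    dep_tot <- dep_e + dep_511 + dep_g
    emit_tot <- emit_e + emit_511 + emit_g
    new_af_result(
      electron_af = sum(dep_e) / sum(emit_e),
      photon_af = sum(dep_511 + dep_g) / sum(emit_511 + emit_g),
      dose_per_decay_Gy = mean(dep_tot) * .MEV_TO_J / mass_kg,
      photon_share = if (sum(dep_tot) > 0) sum(dep_511) / sum(dep_tot) else 1,
      mc_uncertainty = if (mean(dep_tot) > 0)
        sd(dep_tot) / sqrt(n) / mean(dep_tot) else Inf,
      emitted_MeV_per_decay = mean(emit_tot),
      deposited_MeV_per_decay = mean(dep_tot),
      max_history_excess_MeV = max(dep_tot - emit_tot),
      n_histories = n, seed = seed
    )
  })
}
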