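# Internal physics constants for the simplified transport models.
# Water is used as the tissue surrogate (unit density) throughout.

# Mass energy-absorption coefficients for water, cm^2/g (NIST tabulation,
# 0.1-2 MeV). Log-log interpolated; photons outside the range use the
# nearest endpoint.
.muen_water <- data.frame(
  energy_MeV = c(0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60, 0.80,
                 1.00, 1.25, 1.50, 2.00),
  muen_cm2_g = c(0.02546, 0.02764, 0.02967, 0.03192, 0.03279, 0.03299,
                 0.03284, 0.03206, 0.03103, 0.02965, 0.02833, 0.02608)
)

# linear attenuation-for-absorption coefficient (1/cm at unit density)
.muen_water_at <- function(energy_MeV) {
  e <- pmin(pmax(energy_MeV, min(.muen_water$energy_MeV)),
            max(.muen_water$energy_MeV))
  exp(approx(log(.muen_water$energy_MeV), log(.muen_water$muen_cm2_g),
             xout = log(e), rule = 2)$y)
}

# CSDA ranges of electrons/positrons in water, g/cm^2 (0.2-2 MeV), and a
# two-parameter power law R = a E^b fitted to them. The fit reproduces the
# 3.5-mm mean range of the 68Ga positron spectrum.
.csda_water <- data.frame(
  energy_MeV = c(0.2, 0.3, 0.4, 0.5, 0.7, 1.0, 1.5, 2.0),
  range_g_cm2 = c(0.0449, 0.0842, 0.1284, 0.1766, 0.2795, 0.4367,
                  0.7075, 0.9785)
)

.range_law <- local({
  fit <- lm(log(range_g_cm2) ~ log(energy_MeV), data = .csda_water)
  list(a = unname(exp(coef(fit)[1])), b = unname(coef(fit)[2]))
})

# electron range in cm (unit density) from kinetic energy in MeV
.electron_range_cm <- function(energy_MeV) {
  .range_law$a * energy_MeV^.range_law$b
}

# inverse: kinetic energy in MeV from residual range in cm
.electron_energy_from_range <- function(range_cm) {
  (pmax(range_cm, 0) / .range_law$a)^(1 / .range_law$b)
}

# Sample positron kinetic energies (MeV) from an allowed beta spectrum with
# the given endpoint, including the positron Coulomb (Fermi) suppression of
# low energies for daughter charge Z. Tabulated inverse-CDF sampling on a
# fixed grid keeps the draw deterministic under set.seed().
.sample_beta_energy <- function(n, endpoint_MeV = 1.899, Z = 30,
                                n_grid = 2048) {
  me <- 0.510999
  t_grid <- seq(endpoint_MeV / n_grid / 2, endpoint_MeV * (1 - 1e-6),
                length.out = n_grid)
  W <- (t_grid + me) / me
  p <- sqrt(W^2 - 1)
  nu <- Z / 137.036 * W / p
  fermi <- 2 * pi * nu / (exp(2 * pi * nu) - 1)
  dens <- p * W * (endpoint_MeV - t_grid)^2 * fermi
  idx <- sample.int(n_grid, n, replace = TRUE, prob = dens)
  half_bin <- (t_grid[2] - t_grid[1]) / 2
  pmax(t_grid[idx] + runif(n, -half_bin, half_bin), 1e-4)
}

# Photon self-absorbed fraction for a unit-density sphere: uniform emission,
# isotropic directions, single-interaction mu_en weighting along the chord to
# the surface. Deterministic midpoint quadrature over (radius, direction).
.sphere_photon_af <- function(radius_cm, energy_MeV, n_r = 64, n_u = 64) {
  mu <- .muen_water_at(energy_MeV)
  r <- (seq_len(n_r) - 0.5) / n_r * radius_cm
  u <- (seq_len(n_u) - 0.5) / n_u * 2 - 1
  chord <- outer(r, u, function(r, u) -r * u + sqrt(radius_cm^2 - r^2 * (1 - u^2)))
  w <- r^2 / sum(r^2)
  sum(w * rowMeans(1 - exp(-mu * chord)))
}

# Run a function with a temporarily seeded RNG, restoring (or clearing) the
# global .Random.seed afterwards so seeded Monte Carlo calls are bit-for-bit
# reproducible without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
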