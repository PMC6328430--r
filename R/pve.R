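#' Combine Gaussian resolution components in quadrature
#'
#' @param ... FWHM values in mm (e.g. post-filter and scanner intrinsic
#'   resolution).
#' @return Effective FWHM in mm, `sqrt(sum of squares)`.
#' @examples
#' combine_fwhm(6.4, 4.8) # 8 mm effective PSF
#' @export
combine_fwhm <- function(...) {
  v <- c(...)
  if (any(v <= 0)) abort("FWHM components must be positive.",
                         class = "psmadosim_domain_error")
  sqrt(sum(v^2))
}

#' Partial-volume recovery coefficient for a hot sphere
#'
#' Maximum-voxel recovery coefficient of a unit-intensity sphere imaged with
#' an isotropic 3D Gaussian point-spread function. The value is computed two
#' ways and cross-checked: the closed-form central value
#' `RC = erf(R / (sqrt(2) sigma)) - sqrt(2/pi) (R/sigma) exp(-R^2 / (2 sigma^2))`
#' and the maximum of an explicit numerical convolution of the sphere
#' indicator with the Gaussian on a fine grid. The reciprocal `1/RC` is the
#' factor by which a maximum-voxel activity reading must be multiplied to
#' recover the true concentration; a 10-mm sphere under an 8-mm effective
#' PSF gives a factor of about 2, the usual NEMA-phantom-derived correction
#' for lacrimal-gland-sized objects.
#'
#' @param sphere_diameter_mm Sphere diameter in mm.
#' @param psf_fwhm_mm Effective PSF FWHM in mm (see [combine_fwhm()]).
#' @param grid_spacing_mm Grid step of the numerical cross-check; must not
#'   exceed `diameter/5`.
#' @param check_tol Maximum tolerated relative disagreement between the two
#'   routes (default 1%); exceeding it is an error.
#' @return One-row tibble: `sphere_diameter_mm`, `psf_fwhm_mm`, `rc`
#'   (closed form), `rc_numeric`, `correction_factor` (= 1/rc).
#' @examples
#' recovery_coefficient(10, combine_fwhm(6.4, 4.8))
#' @export
recovery_coefficient <- function(sphere_diameter_mm, psf_fwhm_mm,
                                 grid_spacing_mm = 0.5, check_tol = 0.01) {
  if (psf_fwhm_mm <= 0) abort("PSF FWHM must be positive.",
                              class = "psmadosim_domain_error")
  if (sphere_diameter_mm <= 0 || grid_spacing_mm <= 0) {
    abort("diameter and grid spacing must be positive.",
          class = "psmadosim_domain_error")
  }
  if (grid_spacing_mm > sphere_diameter_mm / 5) {
    abort("grid spacing must be at most diameter/5.",
          class = "psmadosim_domain_error")
  }
  R <- sphere_diameter_mm / 2
  sigma <- psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  rc_cf <- .rc_closed_form(R, sigma)
  rc_num <- .rc_numeric(R, sigma, grid_spacing_mm)
  if (abs(rc_num - rc_cf) / rc_cf > check_tol) {
    abort(sprintf(
      "closed-form (%.4f) and numerical (%.4f) recovery disagree by > %.3g.",
      rc_cf, rc_num, check_tol))
  }
  tibble::tibble(
    sphere_diameter_mm = sphere_diameter_mm, psf_fwhm_mm = psf_fwhm_mm,
    rc = rc_cf, rc_numeric = rc_num, correction_factor = 1 / rc_cf
  )
}

.erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# central value of a uniform sphere convolved with an isotropic Gaussian
.rc_closed_form <- function(R, sigma) {
  .erf(R / (sqrt(2) * sigma)) -
    sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2))
}

# brute-force separable convolution of an (antialiased) sphere indicator
.rc_numeric <- function(R, sigma, h) {
  half <- R + 4 * sigma
  x <- seq(-half, half, by = h)
  if (length(x) %% 2 == 0) x <- seq(-half - h / 2, half + h / 2, by = h)
  nx <- length(x)
  d2 <- outer(x^2, x^2, "+")
  vol <- array(0, c(nx, nx, nx))
  for (k in seq_len(nx)) {
    d <- sqrt(d2 + x[k]^2)
    vol[, , k] <- pmin(1, pmax(0, (R - d) / h + 0.5))
  }
  # voxel-integrated Gaussian kernel, applied separably along each axis
  kern <- outer(x, x, function(a, b)
    pnorm((a - b + h / 2) / sigma) - pnorm((a - b - h / 2) / sigma))
  conv_axis <- function(a) {
    m <- kern %*% matrix(a, nx, nx * nx)
    aperm(array(m, c(nx, nx, nx)), c(2, 3, 1))
  }
  out <- conv_axis(conv_axis(conv_axis(vol)))
  max(out)
}
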