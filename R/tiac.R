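#' Time-integrated activity coefficient from a fitted retention model
#'
#' For a decay-corrected retention model `U(t) = sum_i a_i exp(-rate_i t)` the
#' number of decays per administered activity is the closed form
#' `sum_i a_i / (rate_i + lambda_phys)`, converted to hours. The unrounded
#' physical decay constant `ln 2 / half_life` is used throughout.
#'
#' @param model A [retention_model()] / [fit_retention()] result, or a data
#'   frame with columns `amplitude` and `rate_per_min`.
#' @param nuclide Decay data, default [ga68_decay_data()].
#' @return TIAC in hours per unit administered activity.
#' @examples
#' m <- retention_model(data.frame(amplitude = 1, rate_per_min = 0))
#' tiac_from_model(m) # pure physical decay: 1/lambda = 1.63 h
#' @export
tiac_from_model <- function(model, nuclide = ga68_decay_data()) {
  comp <- if (is.data.frame(model)) tibble::as_tibble(model) else model$components
  stopifnot(all(c("amplitude", "rate_per_min") %in% names(comp)))
  if (any(comp$rate_per_min < 0)) {
    abort("biological rates must be >= 0.", class = "psmadosim_domain_error")
  }
  lam <- nuclide$decay_constant_per_min
  sum(comp$amplitude / (comp$rate_per_min + lam)) / 60
}

#' Time-integrated activity coefficient by trapezoidal integration
#'
#' Direct numerical cumulated activity from measured uptake data: the
#' trapezoid sum over the sampled (non-decay-corrected) retention values with
#' `t(0) = U(0) = 0` prepended, plus a pure physical-decay tail `U(n)/lambda`
#' beyond the last sample. Used for organs where no acceptable retention
#' equation exists (salivary glands) and for the bladder between voids.
#'
#' Input must be the physically decaying fractions actually present at each
#' time; decay-corrected data are refused (convert with [decay_uncorrect()]),
#' because only then is the pure-decay tail exact.
#'
#' @param points Data frame with columns `time_min` (strictly increasing) and
#'   `value` (fraction of injected activity, not decay-corrected). An optional
#'   `decay_corrected` column is checked.
#' @param nuclide Decay data supplying the physical decay constant.
#' @return TIAC in hours.
#' @examples
#' t <- seq(5, 240, by = 5)
#' u <- exp(-decay_constant(67.71) * t)
#' tiac_trapezoid(data.frame(time_min = t, value = u)) # ~1/lambda
#' @export
tiac_trapezoid <- function(points, nuclide = ga68_decay_data()) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("time_min", "value") %in% names(points)))
  if ("decay_corrected" %in% names(points) && any(points$decay_corrected)) {
    abort(paste("tiac_trapezoid() needs non-decay-corrected fractions;",
                "convert first with decay_uncorrect()."),
          class = "psmadosim_domain_error")
  }
  t <- points$time_min
  u <- points$value
  if (length(t) == 0) return(0)
  if (any(diff(t) <= 0)) {
    abort("times must be strictly increasing.",
          class = "psmadosim_domain_error")
  }
  if (t[1] > 0) {
    t <- c(0, t)
    u <- c(0, u)
  }
  lam <- nuclide$decay_constant_per_min
  trap <- sum((head(u, -1) + tail(u, -1)) / 2 * diff(t))
  (trap + tail(u, 1) / lam) / 60
}

#' Cumulated activity in the urinary bladder with scheduled voiding
#'
#' The bladder-content curve is built from the cumulative decay-corrected
#' "urine plus bladder content" activity `F(t)`: the physically decaying
#' content at time `t` is `(F(t) - F(v)) exp(-lambda t)` where `v` is the last
#' void before `t`; the content is zeroed at each void time (default 3.5 and
#' 7 h, the ICRP voiding convention). Integration is trapezoidal on a fine
#' grid between voids; beyond the last grid point the inflow is taken as
#' saturated so the tail is pure physical decay, `content/lambda`.
#'
#' @param inflow Either a function of time (minutes) returning the cumulative
#'   decay-corrected fraction of injected activity excreted into the bladder,
#'   or a data frame with columns `time_min` and `value` (linearly
#'   interpolated, constant beyond the last sample).
#' @param void_times_h Strictly increasing void times in hours (default
#'   `c(3.5, 7)`).
#' @param nuclide Decay data supplying the physical decay constant.
#' @param dt_min Integration grid step in minutes.
#' @param horizon_h Optional end of integration in hours; the default runs to
#'   the last void plus ten physical half-lives and adds the analytic tail.
#'   Supplying a horizon at the last void evaluates the pre-void integral only.
#' @return Cumulated activity in the bladder contents, hours per unit
#'   administered activity.
#' @export
bladder_cumulated_activity <- function(inflow, void_times_h = c(3.5, 7),
                                       nuclide = ga68_decay_data(),
                                       dt_min = 0.5, horizon_h = NULL) {
  if (length(void_times_h) == 0 || any(void_times_h <= 0) ||
      any(diff(void_times_h) <= 0)) {
    abort("void times must be positive and strictly increasing.",
          class = "psmadosim_config_error")
  }
  if (is.data.frame(inflow)) {
    df <- tibble::as_tibble(inflow)
    stopifnot(all(c("time_min", "value") %in% names(df)))
    if (min(void_times_h) * 60 < min(df$time_min)) {
      abort("void times fall before the first inflow sample.",
            class = "psmadosim_config_error")
    }
    f <- function(t) approx(df$time_min, df$value, xout = t, rule = 2)$y
  } else {
    stopifnot(is.function(inflow))
    f <- inflow
  }
  lam <- nuclide$decay_constant_per_min
  voids_min <- void_times_h * 60
  horizon_min <- if (is.null(horizon_h)) {
    max(voids_min) + 10 * nuclide$half_life_min
  } else {
    horizon_h * 60
  }
  bounds <- sort(unique(c(0, voids_min[voids_min < horizon_min], horizon_min)))
  total_min <- 0
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    grid <- unique(c(seq(lo, hi, by = dt_min), hi))
    content <- pmax(f(grid) - f(lo), 0) * exp(-lam * grid)
    total_min <- total_min +
      sum((head(content, -1) + tail(content, -1)) / 2 * diff(grid))
  }
  # pure-decay tail beyond the horizon (saturated inflow)
  if (is.null(horizon_h)) {
    last_reset <- max(bounds[-length(bounds)])
    content_end <- max(f(horizon_min) - f(last_reset), 0) * exp(-lam * horizon_min)
    total_min <- total_min + content_end / lam
  }
  total_min / 60
}

#' Remainder-of-body retention by subtraction
#'
#' The activity not assigned to a delineated source is assumed homogeneously
#' distributed in the rest of the body: remainder = total - organs - blood -
#' bladder content - voided urine, all as same-time decay-corrected fractions
#' of injected activity. Negative remainders are clipped to zero with a
#' warning; inputs summing to more than `1.05 * total` raise an inconsistency
#' error.
#'
#' @param organs Summed organ fraction(s) at each time point.
#' @param blood,bladder_content,urine Same-time decay-corrected fractions.
#' @param total Decay-corrected total (default 1).
#' @return Remainder fraction(s), same length as the inputs.
#' @export
remainder_retention <- function(organs, blood = 0, bladder_content = 0,
                                urine = 0, total = 1) {
  acc <- organs + blood + bladder_content + urine
  if (any(acc > 1.05 * total)) {
    abort("source fractions sum to more than 1.05 x total: inconsistent inputs.",
          class = "psmadosim_domain_error")
  }
  rem <- total - acc
  if (any(rem < 0)) {
    warn("negative remainder clipped to zero.")
    rem <- pmax(rem, 0)
  }
  rem
}

#' Rescale a TIAC to a different organ mass
#'
#' Under the assumption that activity concentration is independent of organ
#' size, a TIAC estimated with one organ mass converts to another mass by
#' simple proportion. Used e.g. to restate a reference-phantom liver TIAC
#' (2360 g) for a patient-scale liver.
#'
#' @param tiac_h TIAC in hours.
#' @param mass_from_g Mass the TIAC was computed with.
#' @param mass_to_g Target mass.
#' @return Rescaled TIAC in hours.
#' @examples
#' scale_tiac_to_mass(0.23, 2360, 1000) # ~0.10 h
#' @export
scale_tiac_to_mass <- function(tiac_h, mass_from_g, mass_to_g) {
  if (any(mass_from_g <= 0) || any(mass_to_g <= 0)) {
    abort("masses must be positive.", class = "psmadosim_domain_error")
  }
  tiac_h * mass_to_g / mass_from_g
}
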