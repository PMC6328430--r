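#' Build an exponential retention model from known parameters
#'
#' A retention model is a sum of exponential components
#' `U(t) = sum_i a_i exp(-rate_i t)` with biological rates in 1/min. For
#' uptake-washout ("washin") kinetics the model is the matched-pair form
#' `c (exp(-rate_slow t) - exp(-rate_fast t))`, stored as components with
#' amplitudes `+c` and `-c`; this is the only case in which a negative
#' amplitude is admitted.
#'
#' @param components Data frame with columns `amplitude` (fraction of injected
#'   activity) and `rate_per_min` (biological clearance rate, 1/min).
#' @param organ Optional organ label.
#' @param constrained_to_unity_at_zero Were the amplitudes constrained to sum
#'   to 1 (fit forced through 100% at time zero)?
#' @param washin Is this a matched-pair uptake-washout model?
#' @return An object of class `retention_model`.
#' @examples
#' blood <- retention_model(
#'   data.frame(amplitude = c(0.91, 0.09),
#'              rate_per_min = log(2) / c(6.5, 264)),
#'   organ = "blood", constrained_to_unity_at_zero = TRUE)
#' tiac_from_model(blood)
#' @export
retention_model <- function(components, organ = NULL,
                            constrained_to_unity_at_zero = FALSE,
                            washin = FALSE) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("amplitude", "rate_per_min") %in% names(components)))
  components <- components[order(-components$rate_per_min), ]
  components$half_life_min <- ifelse(components$rate_per_min > 0,
                                     log(2) / components$rate_per_min, Inf)
  x <- structure(
    list(organ = organ, components = components,
         constrained_to_unity_at_zero = constrained_to_unity_at_zero,
         washin = washin),
    class = "retention_model"
  )
  validate_retention_model(x)
}

#' @rdname retention_model
#' @param x A `retention_model`.
#' @export
validate_retention_model <- function(x) {
  comp <- x$components
  if (any(comp$rate_per_min < 0)) {
    abort("biological rates must be >= 0.", class = "psmadosim_domain_error")
  }
  if (x$washin) {
    if (nrow(comp) != 2 || abs(sum(comp$amplitude)) > 1e-9) {
      abort("a washin model must be a matched +c/-c pair of components.")
    }
  } else if (any(comp$amplitude < 0)) {
    abort("amplitudes must be >= 0 (except in matched washin pairs).",
          class = "psmadosim_domain_error")
  }
  if (x$constrained_to_unity_at_zero && abs(sum(comp$amplitude) - 1) > 1e-9) {
    abort("constrained model amplitudes must sum to 1.",
          class = "psmadosim_domain_error")
  }
  x
}

#' Evaluate a retention model
#'
#' @param object A `retention_model` or `retention_fit`.
#' @param time_min Times post-injection in minutes.
#' @param ... Unused.
#' @return Retention (fraction of injected activity) at `time_min`.
#' @export
predict.retention_model <- function(object, time_min, ...) {
  comp <- object$components
  vapply(time_min,
         function(t) sum(comp$amplitude * exp(-comp$rate_per_min * t)),
         numeric(1))
}

#' @export
print.retention_model <- function(x, ...) {
  kind <- if (isTRUE(x$washin)) "uptake-washout" else
    paste0(nrow(x$components), "-exponential")
  cat(sprintf("<retention_model> %s%s%s\n",
              if (!is.null(x$organ)) paste0(x$organ, ": ") else "", kind,
              if (x$constrained_to_unity_at_zero) " (forced through 1 at t = 0)" else ""))
  print(x$components)
  invisible(x)
}

#' Fit a mono- or bi-exponential retention function
#'
#' Unweighted least squares on the linear scale (Levenberg-Marquardt via
#' \pkg{minpack.lm}), with amplitudes bounded at zero and, optionally, the
#' amplitude sum constrained to 1 so the curve is forced through 100% at time
#' zero (the convention used for pooled blood data). With
#' `n_components = NULL` the model order is chosen by an F-test at
#' `alpha = 0.05`. `washin = TRUE` fits the matched-pair uptake-washout form
#' `c (exp(-rate_slow t) - exp(-rate_fast t))`, appropriate for organs whose
#' retention starts at zero and peaks before washing out.
#'
#' @param points Data frame with columns `time_min` and `value` holding
#'   decay-corrected retention as fraction of injected activity.
#' @param n_components 1, 2, or `NULL` to choose by F-test.
#' @param constrain_unity Force the amplitudes to sum to 1.
#' @param washin Fit the uptake-washout pair instead of a nonnegative sum.
#' @param organ Optional organ label carried into the result.
#' @return An object of classes `retention_fit` and `retention_model`, with
#'   the fitted `components`, `fitted` values, `residuals`, `sse`, and
#'   convergence information. Non-convergence raises a condition of class
#'   `psmadosim_fit_failure` carrying the residual diagnostics; there is no
#'   silent fallback.
#' @examples
#' t <- c(2, 5, 10, 20, 30, 45, 85, 175, 245)
#' u <- 0.91 * exp(-log(2) / 6.5 * t) + 0.09 * exp(-log(2) / 264 * t)
#' fit <- fit_retention(data.frame(time_min = t, value = u),
#'                      n_components = 2, constrain_unity = TRUE)
#' tidy(fit)
#' @export
fit_retention <- function(points, n_components = NULL, constrain_unity = FALSE,
                          washin = FALSE, organ = NULL) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("time_min", "value") %in% names(points)))
  if (any(points$value < 0)) {
    abort("retention values must be nonnegative.",
          class = "psmadosim_domain_error")
  }
  points <- points[order(points$time_min), ]
  if (is.null(n_components)) {
    return(.select_order(points, constrain_unity, washin, organ))
  }
  stopifnot(n_components %in% c(1, 2))
  if (washin && n_components != 2) {
    abort("washin fits are bi-exponential (n_components = 2).")
  }
  n_par <- if (washin) 3 else if (constrain_unity) 2 * n_components - 1
           else 2 * n_components
  if (nrow(points) < 2 * n_components) {
    abort(sprintf("need at least %d points for a %d-component fit.",
                  2 * n_components, n_components),
          class = "psmadosim_fit_failure")
  }
  t <- points$time_min
  y <- points$value

  base_rate <- .initial_rate(t, y)
  model_fun <- .make_model_fun(n_components, constrain_unity, washin)
  starts <- .make_starts(n_components, constrain_unity, washin, base_rate, y)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st$par, lower = st$lower, upper = st$upper,
        fn = function(p) y - model_fun(p, t),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4 || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort(
      message = paste0("retention fit failed to converge (",
                       n_components, " components",
                       if (constrain_unity) ", constrained", ")."),
      class = "psmadosim_fit_failure",
      data = list(points = points, starts = starts)
    )
  }

  comp <- .par_to_components(best$par, n_components, constrain_unity, washin)
  model <- retention_model(comp, organ = organ,
                           constrained_to_unity_at_zero = constrain_unity,
                           washin = washin)
  fitted <- predict(model, t)
  resid <- y - fitted
  structure(
    c(model,
      list(n_components = n_components, data = points, fitted = fitted,
           residuals = resid, sse = sum(resid^2),
           sigma = sqrt(sum(resid^2) / max(1, length(y) - n_par)),
           n = length(y), converged = TRUE, info = best$info,
           message = best$message)),
    class = c("retention_fit", "retention_model")
  )
}

.initial_rate <- function(t, y) {
  pos <- y > 0 & t > 0
  if (sum(pos) >= 2 && sd(t[pos]) > 0) {
    sl <- -coef(lm(log(y[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl > 1e-8) return(unname(sl))
  }
  0.01
}

.make_model_fun <- function(k, constrained, washin) {
  if (washin) {
    function(p, t) p[1] * (exp(-p[2] * t) - exp(-(p[2] + p[3]) * t))
  } else if (k == 1 && constrained) {
    function(p, t) exp(-p[1] * t)
  } else if (k == 1) {
    function(p, t) p[1] * exp(-p[2] * t)
  } else if (constrained) {
    function(p, t) p[1] * exp(-p[2] * t) + (1 - p[1]) * exp(-p[3] * t)
  } else {
    function(p, t) p[1] * exp(-p[3] * t) + p[2] * exp(-p[4] * t)
  }
}

.make_starts <- function(k, constrained, washin, base_rate, y) {
  y0 <- max(y[1], max(y) / 2, 1e-6)
  rate_pairs <- list(c(5, 0.5), c(20, 0.1), c(2, 0.9) * c(1, 0.5))
  if (washin) {
    lapply(rate_pairs, function(rp) list(
      par = c(max(y), base_rate * rp[2], base_rate * rp[1]),
      lower = c(0, 0, 1e-9), upper = c(Inf, Inf, Inf)))
  } else if (k == 1 && constrained) {
    list(list(par = base_rate, lower = 0, upper = Inf),
         list(par = base_rate * 5, lower = 0, upper = Inf))
  } else if (k == 1) {
    list(list(par = c(y0, base_rate), lower = c(0, 0), upper = c(Inf, Inf)),
         list(par = c(max(y), base_rate * 0.2), lower = c(0, 0),
              upper = c(Inf, Inf)))
  } else if (constrained) {
    lapply(rate_pairs, function(rp) list(
      par = c(0.7, base_rate * rp[1], base_rate * rp[2]),
      lower = c(0, 0, 0), upper = c(1, Inf, Inf)))
  } else {
    lapply(rate_pairs, function(rp) list(
      par = c(0.7 * y0, 0.3 * y0, base_rate * rp[1], base_rate * rp[2]),
      lower = rep(0, 4), upper = rep(Inf, 4)))
  }
}

.par_to_components <- function(p, k, constrained, washin) {
  if (washin) {
    rs <- p[2]; rf <- p[2] + p[3]
    tibble::tibble(amplitude = c(-p[1], p[1]), rate_per_min = c(rf, rs))
  } else if (k == 1 && constrained) {
    tibble::tibble(amplitude = 1, rate_per_min = p[1])
  } else if (k == 1) {
    tibble::tibble(amplitude = p[1], rate_per_min = p[2])
  } else if (constrained) {
    tibble::tibble(amplitude = c(p[1], 1 - p[1]), rate_per_min = p[2:3])
  } else {
    tibble::tibble(amplitude = p[1:2], rate_per_min = p[3:4])
  }
}

# Model-order selection: mono vs bi-exponential by F-test at alpha = 0.05.
.select_order <- function(points, constrain_unity, washin, organ,
                          alpha = 0.05) {
  fit1 <- tryCatch(
    fit_retention(points, 1, constrain_unity, washin = FALSE, organ = organ),
    psmadosim_fit_failure = function(e) NULL)
  fit2 <- tryCatch(
    fit_retention(points, 2, constrain_unity, washin, organ = organ),
    psmadosim_fit_failure = function(e) NULL)
  if (is.null(fit2)) return(fit1)
  if (is.null(fit1)) return(fit2)
  p1 <- if (constrain_unity) 1 else 2
  p2 <- if (washin) 3 else if (constrain_unity) 3 else 4
  df2 <- fit2$n - p2
  if (df2 <= 0) return(fit1)
  if (fit2$sse <= .Machine$double.eps * max(1, fit1$sse)) return(fit2)
  f <- ((fit1$sse - fit2$sse) / (p2 - p1)) / (fit2$sse / df2)
  p_val <- pf(f, p2 - p1, df2, lower.tail = FALSE)
  if (is.finite(p_val) && p_val < alpha) fit2 else fit1
}

#' @export
#' @method tidy retention_fit
#' @rdname fit_retention
#' @param x A `retention_fit`.
#' @param ... Unused.
tidy.retention_fit <- function(x, ...) {
  dplyr::mutate(x$components,
                term = paste0("component_", dplyr::row_number()),
                organ = x$organ %||% NA_character_, .before = 1)
}

#' @export
#' @method glance retention_fit
#' @rdname fit_retention
glance.retention_fit <- function(x, ...) {
  tibble::tibble(
    organ = x$organ %||% NA_character_,
    n = x$n, n_components = x$n_components, sse = x$sse, sigma = x$sigma,
    constrained = x$constrained_to_unity_at_zero, washin = x$washin,
    converged = x$converged
  )
}

#' @export
print.retention_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  n = %d, SSE = %.4g, converged: %s\n", x$n, x$sse, x$converged))
  invisible(x)
}
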