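#' Plot a fitted retention curve over its data
#'
#' @param object A `retention_fit`.
#' @param ... Unused.
#' @return A ggplot: measured retention points and the fitted exponential
#'   curve, time in minutes post-injection.
#' @method autoplot retention_fit
#' @export
autoplot.retention_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_min = seq(0, max(object$data$time_min), length.out = 200))
  grid$value <- predict(object, grid$time_min)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "time post-injection [min]", y = "fraction of injected activity",
      title = object$organ %||% "retention fit") +
    ggplot2::theme_minimal()
}

#' Plot cohort organ dose coefficients
#'
#' @param object A `dose_report`.
#' @param ... Unused.
#' @return A ggplot: cohort-median absorbed-dose coefficient per organ with
#'   the per-patient range as error bars.
#' @method autoplot dose_report
#' @export
autoplot.dose_report <- function(object, ...) {
  s <- dplyr::arrange(object$summary, .data$median_mGy_per_MBq)
  s$organ <- factor(s$organ, levels = s$organ)
  ggplot2::ggplot(s, ggplot2::aes(.data$median_mGy_per_MBq, .data$organ)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$range_low_mGy_per_MBq,
                   xmax = .data$range_high_mGy_per_MBq),
      height = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "absorbed dose coefficient [mGy/MBq]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot synthetic-cohort time-activity samples
#'
#' @param object A `synthetic_cohort`.
#' @param organs Organs to show; default all sampled organs.
#' @param ... Unused.
#' @return A ggplot of the sampled values (per patient) against time,
#'   faceted by organ with free y scales.
#' @method autoplot synthetic_cohort
#' @export
autoplot.synthetic_cohort <- function(object, organs = NULL, ...) {
  s <- object$samples
  if (!is.null(organs)) s <- s[s$organ %in% organs, ]
  ggplot2::ggplot(s, ggplot2::aes(.data$time_min, .data$value,
                                  colour = .data$patient_id)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~organ, scales = "free_y") +
    ggplot2::labs(x = "time post-injection [min]", y = "sampled value",
                  colour = "patient") +
    ggplot2::theme_minimal()
}
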