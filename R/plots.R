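#' Plot a time-activity curve
#'
#' Frame values at their midpoints, with frame extents as horizontal bars.
#'
#' @param object A `pet_tac`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pet_tac <- function(object, ...) {
  df <- tibble::tibble(mid = frame_mid(object), start = object$start,
                       end = object$end, value = object$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$value), linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "activity (kBq/mL)") +
    ggplot2::theme_minimal()
}

#' Plot an input function
#'
#' @param object A `pet_if`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pet_if <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "blood activity (kBq/mL)") +
    ggplot2::theme_minimal()
}

#' Plot a 2T3k fit: measured frames and the fitted model curve
#'
#' @param object A `fit_2t3k`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fit_2t3k <- function(object, ...) {
  df <- tibble::tibble(mid = frame_mid(object$data),
                       measured = object$data$value,
                       fitted = object$fitted$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (min)", y = "activity (kBq/mL)",
                  subtitle = sprintf("Ki = %.4f mL/g/min", object$params$Ki)) +
    ggplot2::theme_minimal()
}

#' Patlak plot with the fitted asymptote
#'
#' @param object A `patlak_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.patlak_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$ki, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "normalised time (min)", y = "normalised tissue",
                  subtitle = sprintf("Ki = %.4f, intercept = %.3f",
                                     object$ki, object$intercept)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "pair mean", y = "difference") +
    ggplot2::theme_minimal()
}

#' Method-vs-reference scatter panels for a comparison study
#'
#' Surrogate Ki (or analogue) against the reference full-scan Ki, one
#' panel per method, coloured by tissue.
#'
#' @param object A `comparison_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comparison_study <- function(object, ...) {
  ref <- dplyr::select(
    dplyr::filter(object$per_subject, .data$method == "reference"),
    "subject", "tissue", ref_Ki = "Ki")
  long <- dplyr::left_join(
    dplyr::filter(object$per_subject, .data$method != "reference"),
    ref, by = c("subject", "tissue"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ref_Ki, y = .data$Ki,
                                     colour = .data$tissue)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "reference Ki (mL/g/min)", y = "surrogate value") +
    ggplot2::theme_minimal()
}
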