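#' Stacked contribution plot for a fitted mixture series
#'
#' @param object A [mixture_series()] tibble.
#' @param ... Unused.
#' @return A ggplot: posterior-mean source contributions stacked per day.
#' @method autoplot mixture_series
#' @export
autoplot.mixture_series <- function(object, ...) {
  dat <- object
  if ("tree_id" %in% names(dat)) {
    dat <- dat |>
      dplyr::group_by(.data$day, .data$source_id) |>
      dplyr::summarise(mean = mean(.data$mean), .groups = "drop") |>
      dplyr::group_by(.data$day) |>
      dplyr::mutate(mean = .data$mean / sum(.data$mean)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$mean,
                                    fill = .data$source_id)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = NULL, y = "contribution to root water uptake",
                  fill = "source") +
    ggplot2::theme_minimal()
}

#' Cumulative water-age curve plot
#'
#' @param object An [age_distribution()].
#' @param ... Unused.
#' @return A ggplot of the nondecreasing cumulative age curve.
#' @method autoplot age_distribution
#' @export
autoplot.age_distribution <- function(object, ...) {
  curve <- cumulative_age_curve(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$age_days, y = .data$cum_fraction)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "water age (days)", y = "cumulative fraction of uptake") +
    ggplot2::theme_minimal()
}

#' Fitted asymptotic uptake curve plot
#'
#' @param object An [fit_uptake_curve()] result.
#' @param ... Unused.
#' @return A ggplot of observed cumulative uptake and the fitted curve.
#' @method autoplot uptake_curve
#' @export
autoplot.uptake_curve <- function(object, ...) {
  obs <- tibble::tibble(t = object$t, uptake = object$observed)
  tt <- seq(min(object$t), max(object$t), length.out = 200)
  co <- object$coef
  fit <- tibble::tibble(t = tt,
                        uptake = co["a"] - (co["a"] - co["b"]) * exp(-co["c"] * tt))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$uptake)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, colour = "steelblue") +
    ggplot2::labs(x = "days since event", y = "cumulative fraction used") +
    ggplot2::theme_minimal()
}

#' Period segmentation plot
#'
#' @param object A [segment_periods()] result.
#' @param ... Unused.
#' @return A ggplot of the labelled period spans.
#' @method autoplot period_segmentation
#' @export
autoplot.period_segmentation <- function(object, ...) {
  dat <- dplyr::mutate(object, period = factor(.data$period, levels = .data$period))
  ggplot2::ggplot(dat, ggplot2::aes(xmin = .data$start, xmax = .data$end + 1,
                                    ymin = 0, ymax = 1, fill = .data$period)) +
    ggplot2::geom_rect(alpha = 0.7) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = NULL, fill = "period") +
    ggplot2::theme_minimal()
}
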