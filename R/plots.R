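#' Plot a BA - CA reference curve
#'
#' Mean BA - CA per age bin with the plus/minus 2 SD reference band;
#' multi-city curves are colored by city.
#'
#' @param object a `binned_curve` from [ba_minus_ca_curve()] or
#'   [city_curves()].
#' @param band draw the mean +- 2 SD band (single-curve input only).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot binned_curve
#' @export
autoplot.binned_curve <- function(object, band = !("city" %in% names(object)),
                                  ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center,
                                        y = .data$mean_diff))
  if ("city" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$city)) +
      ggplot2::geom_point(ggplot2::aes(color = .data$city), size = 1)
  } else {
    if (band) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$mean_diff - 2 * .data$sd_diff,
                     ymax = .data$mean_diff + 2 * .data$sd_diff),
        fill = "grey85")
    }
    p <- p + ggplot2::geom_line() + ggplot2::geom_point(size = 1)
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Bone age - chronological age (years)")
}

#' Plot a calibrated scale
#'
#' GP calibrations: the correction profile (correction versus GP bone
#' age). SMS calibrations: the anchor curve (SMS versus bone age).
#'
#' @param object a `ba_calibration`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ba_calibration
#' @export
autoplot.ba_calibration <- function(object, ...) {
  if (object$kind == "gp") {
    ggplot2::ggplot(tibble::as_tibble(object$table),
                    ggplot2::aes(x = .data$gp_ba, y = .data$correction)) +
      ggplot2::geom_step() + ggplot2::geom_point(size = 1) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::labs(x = "GP bone age (years)", y = "Correction (years)")
  } else {
    ggplot2::ggplot(tibble::as_tibble(object$table),
                    ggplot2::aes(x = .data$bone_age, y = .data$sms)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "Bone age (years)", y = "Sum Maturity Score")
  }
}

#' Bland-Altman plot of paired ratings
#'
#' Difference versus pair mean, with the boxcar running-average curve
#' and the zero line.
#'
#' @param object a `rating_pairs` tibble from [pair_ratings()].
#' @param window running-average window in years (see
#'   [running_average()]).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rating_pairs
#' @export
autoplot.rating_pairs <- function(object, window = 1.0, ...) {
  ra <- running_average(object, window = window)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mid, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(data = ra, linewidth = 1) +
    ggplot2::labs(x = "Mean of the two ratings (years)",
                  y = "Difference, A - B (years)")
}
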