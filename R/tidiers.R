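#' Tidy a bone-age calibration
#'
#' Returns the applicable scale table: for a GP calibration the
#' correction table (`sex`, `gp_ba`, `correction`, `terminal`), for an
#' SMS calibration the anchor table (`sex`, `bone_age`, `sms`).
#'
#' @param x a `ba_calibration` from [calibrate_gp_scale()] or
#'   [calibrate_sms_scale()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy ba_calibration
#' @export
tidy.ba_calibration <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' One-row summary of a bone-age calibration
#'
#' For a GP calibration: record count, grid extent, terminal correction
#' and the resulting scale end (against the parent GP scale ends of 19
#' years for boys and 18 for girls). For an SMS calibration: record
#' count, anchor count and the age at which the scale reaches SMS 1000.
#'
#' @inheritParams tidy.ba_calibration
#' @return a one-row tibble.
#' @method glance ba_calibration
#' @export
glance.ba_calibration <- function(x, ...) {
  if (x$kind == "gp") {
    gp_end <- if (x$sex == "male") 19 else 18
    tibble::tibble(
      kind = "gp", sex = x$sex, n_records = x$n_records,
      n_rows = nrow(x$table),
      grid_lo = min(x$table$gp_ba), grid_hi = max(x$table$gp_ba),
      terminal_correction = x$table$correction[nrow(x$table)],
      scale_end = scale_end(x$table, gp_end)
    )
  } else {
    tibble::tibble(
      kind = "sms", sex = x$sex, n_records = x$n_records,
      n_anchors = nrow(x$table),
      scale_end = x$table$bone_age[nrow(x$table)]
    )
  }
}

#' @method tidy binned_curve
#' @export
tidy.binned_curve <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a rating-pair set
#'
#' Bias, rms and pair count over the full mid range, plus the number of
#' records skipped for missing ratings.
#'
#' @param x a `rating_pairs` tibble from [pair_ratings()].
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance rating_pairs
#' @export
glance.rating_pairs <- function(x, ...) {
  dplyr::mutate(bias_rms(x), n_skipped = attr(x, "n_skipped") %||% 0L)
}
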