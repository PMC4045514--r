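#' BA - CA reference curve in fixed-width age bins
#'
#' Computes the mean, sample SD and count of (maturity measure - CA) in
#' age bins of width `bin_width` centered on the anniversary grid: a
#' record with chronological age `ca` falls in the bin centered on the
#' nearest multiple of `bin_width` (half-open intervals
#' \eqn{[c - w/2, c + w/2)}), so each bin owns one anniversary even for
#' jittered sampling ages. Bins with fewer than `n_min` records are
#' dropped, not zero-filled. The plus/minus 2 SD reference band is
#' derived output (`mean_diff +- 2 * sd_diff`), not stored.
#'
#' @param cohort cohort data frame (see [as_cohort()]).
#' @param sex `"male"` or `"female"`.
#' @param measure column holding the maturity measure in years; one of
#'   `"gp_ba"`, `"tw3_auto"`, `"tw3_manual"`.
#' @param bin_width bin width in years, default 1.
#' @param n_min minimum records per bin, default 10.
#' @return a tibble of class `binned_curve` with columns `sex`,
#'   `bin_center`, `mean_diff`, `sd_diff`, `n`, ordered by `bin_center`.
#' @examples
#' coh <- simulate_cohort(n_per_age = 30, seed = 7)
#' ba_minus_ca_curve(coh, "female")
#' @export
ba_minus_ca_curve <- function(cohort, sex, measure = "gp_ba",
                              bin_width = 1.0, n_min = 10) {
  sex <- match_sex(sex)
  stopifnot(measure %in% c("gp_ba", "tw3_auto", "tw3_manual", "sms"))
  rows <- dplyr::filter(tibble::as_tibble(cohort),
                        .data$sex == .env$sex, !is.na(.data[[measure]]))
  curve <- rows |>
    # floor(x/w + 1/2), not round(): the bin interval is half-open on the
    # right, so an age exactly on a boundary belongs to the upper bin
    dplyr::mutate(bin_center = floor(.data$ca / bin_width + 0.5) * bin_width,
                  diff = .data[[measure]] - .data$ca) |>
    dplyr::group_by(.data$bin_center) |>
    dplyr::summarise(mean_diff = mean(.data$diff),
                     sd_diff = sd(.data$diff),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= n_min) |>
    dplyr::arrange(.data$bin_center) |>
    dplyr::mutate(sex = .env$sex, .before = 1)
  if (nrow(curve) == 0) {
    abort(sprintf(
      "No age bin holds >= %d %s records with `%s` present; cannot build a curve.",
      n_min, sex, measure), class = "boneagecal_empty_curve_error")
  }
  structure(curve, measure = measure, bin_width = bin_width,
            class = c("binned_curve", class(curve)))
}

#' Average SD of a reference curve over an age interval
#'
#' Unweighted arithmetic mean of the per-bin SDs whose bin centers fall
#' in the closed interval -- the convention used to quote a single SD
#' for a reference band computed in 1-year intervals.
#'
#' @param curve a `binned_curve` from [ba_minus_ca_curve()].
#' @param age_lo,age_hi closed age interval in years.
#' @return average SD in years.
#' @export
average_sd <- function(curve, age_lo, age_hi) {
  in_range <- curve$bin_center >= age_lo & curve$bin_center <= age_hi
  if (!any(in_range)) {
    abort(sprintf("No bin centers inside [%g, %g].", age_lo, age_hi),
          class = "boneagecal_domain_error")
  }
  mean(curve$sd_diff[in_range])
}

#' Per-city BA - CA reference curves
#'
#' Splits the cohort by city label and computes one reference curve per
#' city with the same binning as [ba_minus_ca_curve()] -- the structure
#' used to compare maturation tempo across regions.
#'
#' @inheritParams ba_minus_ca_curve
#' @return a tibble of class `binned_curve` with an additional leading
#'   `city` column.
#' @export
city_curves <- function(cohort, sex, measure = "gp_ba",
                        bin_width = 1.0, n_min = 10) {
  cohort <- tibble::as_tibble(cohort)
  labels <- unique(cohort$city[!is.na(cohort$city) & cohort$city != ""])
  if (length(labels) == 0) {
    abort("Cohort has no city labels.", class = "boneagecal_domain_error")
  }
  curves <- purrr::map(setNames(labels, labels), function(ct) {
    ba_minus_ca_curve(dplyr::filter(cohort, .data$city == ct),
                      sex = sex, measure = measure,
                      bin_width = bin_width, n_min = n_min)
  })
  out <- dplyr::bind_rows(curves, .id = "city")
  structure(out, measure = measure, bin_width = bin_width,
            class = c("binned_curve", class(tibble::tibble())))
}
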