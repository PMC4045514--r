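#' Pair two bone-age ratings of the same radiographs
#'
#' Builds the per-image rating pairs behind a Bland-Altman analysis:
#' for every record carrying both ratings, the pair mean
#' `mid = (a + b) / 2` (the x-axis of the plot) and the difference
#' `diff = a - b`. By convention rating A is the automated rating and
#' rating B the manual one, so `diff` is automated minus manual.
#' Records missing either rating are skipped; the skip count is kept as
#' the `n_skipped` attribute.
#'
#' @param cohort cohort data frame (see [as_cohort()]).
#' @param field_a,field_b rating columns, default `tw3_auto` vs
#'   `tw3_manual`.
#' @return a tibble of class `rating_pairs` with columns `subject_id`,
#'   `rating_a`, `rating_b`, `mid`, `diff`.
#' @export
pair_ratings <- function(cohort, field_a = "tw3_auto",
                         field_b = "tw3_manual") {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(field_a %in% names(cohort), field_b %in% names(cohort))
  keep <- !is.na(cohort[[field_a]]) & !is.na(cohort[[field_b]])
  if (!any(keep)) {
    abort(sprintf("No record carries both `%s` and `%s`.", field_a, field_b),
          class = "boneagecal_domain_error")
  }
  out <- tibble::tibble(
    subject_id = cohort$subject_id[keep],
    rating_a = cohort[[field_a]][keep],
    rating_b = cohort[[field_b]][keep]
  ) |>
    dplyr::mutate(mid = (.data$rating_a + .data$rating_b) / 2,
                  diff = .data$rating_a - .data$rating_b)
  structure(out, n_skipped = sum(!keep),
            fields = c(field_a, field_b),
            class = c("rating_pairs", class(out)))
}

#' Bias and rms deviation over a stated mid range
#'
#' The two scalar agreement summaries of a Bland-Altman analysis,
#' restricted to pairs whose mean rating lies in the closed interval
#' \[`mid_lo`, `mid_hi`\]: the bias (mean difference) and the
#' root-mean-square deviation `sqrt(mean(diff^2))` about zero (an `n`
#' denominator -- this is an rms, not a variance estimate), so that
#' `rms^2 = bias^2 + population variance` holds identically.
#'
#' @param pairs a `rating_pairs` tibble from [pair_ratings()].
#' @param mid_lo,mid_hi analysis range in years; defaults span all
#'   pairs.
#' @return a one-row tibble: `bias`, `rms`, `n`, `mid_lo`, `mid_hi`.
#' @export
bias_rms <- function(pairs, mid_lo = -Inf, mid_hi = Inf) {
  d <- pairs$diff[pairs$mid >= mid_lo & pairs$mid <= mid_hi]
  if (length(d) < 2) {
    abort("Fewer than 2 pairs in the requested mid range.",
          class = "boneagecal_domain_error")
  }
  tibble::tibble(bias = mean(d), rms = sqrt(mean(d^2)), n = length(d),
                 mid_lo = mid_lo, mid_hi = mid_hi)
}

#' Running average of rating differences along the mid axis
#'
#' The smooth curve customarily drawn through a Bland-Altman cloud: at
#' each point of a regular grid over the observed mid range, the mean
#' difference of all pairs within a boxcar window of width `window`
#' centered on the point. Grid points supported by fewer than `min_n`
#' pairs are omitted.
#'
#' @param pairs a `rating_pairs` tibble.
#' @param window boxcar window width in years, default 1.
#' @param grid_step evaluation grid spacing in years, default 0.25.
#' @param min_n minimum pairs per evaluation point, default 5.
#' @return a tibble with columns `mid`, `diff`, `n`.
#' @export
running_average <- function(pairs, window = 1.0, grid_step = 0.25,
                            min_n = 5) {
  if (nrow(pairs) < 2) {
    abort("Need at least 2 pairs.", class = "boneagecal_domain_error")
  }
  grid <- seq(floor(min(pairs$mid) / grid_step) * grid_step,
              ceiling(max(pairs$mid) / grid_step) * grid_step,
              by = grid_step)
  purrr::map_dfr(grid, function(g) {
    d <- pairs$diff[abs(pairs$mid - g) <= window / 2]
    tibble::tibble(mid = g, diff = mean(d), n = length(d))
  }) |>
    dplyr::filter(.data$n >= min_n)
}
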