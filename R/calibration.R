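#' Median maturity measure tabulated against chronological age
#'
#' The first step of median-mapping calibration: for each grid age, the
#' interpolated sample median of the chosen maturity measure (GP bone
#' age in years, or SMS score) over the records whose chronological age
#' falls in the half-open bin \eqn{[g - w/2, g + w/2)}. Grid ages with
#' fewer than `n_min` qualifying records are dropped with a warning.
#'
#' @param cohort cohort data frame (see [as_cohort()]).
#' @param sex `"male"` or `"female"`.
#' @param measure column holding the maturity measure: `"gp_ba"`,
#'   `"sms"`, `"tw3_auto"` or `"tw3_manual"`.
#' @param grid chronological ages at which to tabulate, default the
#'   sampling design's [anniversary_ages()]. Records are assigned to
#'   their nearest grid age (never farther than `bin_width / 2`), which
#'   on a uniform grid reduces to half-open bins \eqn{[g - w/2, g + w/2)}
#'   and on the default grid keeps the extra 2.5- and 3.5-year sampling
#'   points from contaminating the neighboring anniversary bins.
#' @param bin_width maximum bin width in years, default 1.
#' @param n_min minimum records per grid age, default 10.
#' @return a tibble of class `median_curve` with columns `sex`, `ca`,
#'   `median` and `n`; attribute `measure` records the tabulated column.
#' @export
median_by_age <- function(cohort, sex, measure = "gp_ba",
                          grid = anniversary_ages(),
                          bin_width = 1.0, n_min = 10) {
  sex <- match_sex(sex)
  stopifnot(measure %in% c("gp_ba", "sms", "tw3_auto", "tw3_manual"))
  rows <- dplyr::filter(tibble::as_tibble(cohort),
                        .data$sex == .env$sex, !is.na(.data[[measure]]))
  grid <- sort(grid)
  # nearest grid age, a record exactly on a midpoint going to the upper
  # bin, capped at bin_width/2 distance
  nearest <- findInterval(rows$ca, head(grid, -1) / 2 + grid[-1] / 2) + 1L
  in_bin <- abs(rows$ca - grid[nearest]) < bin_width / 2 |
    # left-closed: a record exactly bin_width/2 below its grid age counts
    rows$ca == grid[nearest] - bin_width / 2
  curve <- purrr::map_dfr(seq_along(grid), function(k) {
    vals <- rows[[measure]][in_bin & nearest == k]
    tibble::tibble(ca = grid[k], median = median(vals), n = length(vals))
  })
  dropped <- curve$ca[curve$n < n_min]
  if (length(dropped) > 0) {
    warn(sprintf("Dropping %d grid age(s) with fewer than %d records: %s.",
                 length(dropped), n_min, paste(dropped, collapse = ", ")))
    curve <- dplyr::filter(curve, .data$n >= n_min)
  }
  if (nrow(curve) < 2) {
    abort("Fewer than 2 grid ages survive; calibration is impossible.",
          class = "boneagecal_calibration_error")
  }
  new_median_curve(dplyr::mutate(curve, sex = .env$sex, .before = 1),
                   measure = measure, monotone = FALSE)
}

new_median_curve <- function(df, measure, monotone) {
  structure(df, measure = measure, monotone = monotone,
            class = c("median_curve", class(tibble::tibble())))
}

#' Isotonic (monotone non-decreasing) fit of a median curve
#'
#' Sampling noise can make the tabulated medians wiggle locally, while
#' the inversion step presumes a non-decreasing relationship between
#' chronological age and median maturity. This replaces the median
#' values by their least-squares isotonic fit (pool-adjacent-violators),
#' leaving the age grid unchanged. Already-monotone curves are returned
#' unchanged.
#'
#' @param curve a `median_curve` from [median_by_age()].
#' @return the curve with non-decreasing `median` values.
#' @export
monotonize <- function(curve) {
  stopifnot(inherits(curve, "median_curve"))
  fit <- isoreg(curve$ca, curve$median)
  out <- dplyr::mutate(curve, median = fit$yf)
  new_median_curve(out, measure = attr(curve, "measure"), monotone = TRUE)
}

#' Invert a median curve: observed maturity measure to population bone age
#'
#' The defining transform of a median-mapped bone age scale: the
#' population bone age assigned to an observed maturity value is the
#' chronological age at which the population median equals that value.
#' So if the median GP bone age at age 13 is 13.5 years, a child rated
#' GP BA 13.5 is assigned a population bone age of 13.0 years.
#'
#' Inversion is piecewise-linear interpolation on the tabulated
#' (median, age) pairs. Flat segments (ties after monotonization)
#' resolve to the midpoint of the tied age range. Observed values below
#' (above) the tabulated range clamp to the first (last) grid age with a
#' warning.
#'
#' @param curve a monotone `median_curve`; non-monotone input is passed
#'   through [monotonize()] first.
#' @param observed observed maturity value(s), same units as the curve's
#'   measure.
#' @return numeric population bone age(s) in years, with attribute
#'   `out_of_range` (logical, same length) marking clamped values.
#' @examples
#' mc <- median_curve_from_pairs(12:14, c(12.4, 13.5, 14.6))
#' invert_to_bone_age(mc, 13.5)   # 13.0
#' @export
invert_to_bone_age <- function(curve, observed) {
  stopifnot(inherits(curve, "median_curve"), nrow(curve) >= 1)
  if (!isTRUE(attr(curve, "monotone")) && is.unsorted(curve$median)) {
    curve <- monotonize(curve)
  }
  med <- curve$median
  age <- curve$ca
  n <- length(med)
  out <- numeric(length(observed))
  oor <- logical(length(observed))
  for (i in seq_along(observed)) {
    v <- observed[i]
    if (is.na(v)) { out[i] <- NA_real_; next }
    if (v < med[1]) { out[i] <- age[1]; oor[i] <- TRUE; next }
    if (v > med[n]) { out[i] <- age[n]; oor[i] <- TRUE; next }
    hits <- which(abs(med - v) < 1e-12)
    if (length(hits) > 0) {
      # exact hit; a run of tied medians maps to the midpoint of its ages
      out[i] <- (age[min(hits)] + age[max(hits)]) / 2
    } else {
      j <- max(which(med < v))
      out[i] <- age[j] + (v - med[j]) / (med[j + 1] - med[j]) *
        (age[j + 1] - age[j])
    }
  }
  if (any(oor)) {
    warn(sprintf("%d observed value(s) outside the tabulated median range; clamped to the grid ends.",
                 sum(oor)))
  }
  attr(out, "out_of_range") <- oor
  out
}

#' Construct a median curve directly from (age, median) pairs
#'
#' Convenience constructor for already-tabulated medians, e.g. when
#' applying the inversion transform to a published tabulation rather
#' than raw cohort records.
#'
#' @param ca strictly increasing chronological ages in years.
#' @param median median maturity values at those ages.
#' @param sex optional sex label.
#' @param measure measure name, default `"gp_ba"`.
#' @return a `median_curve` tibble.
#' @export
median_curve_from_pairs <- function(ca, median, sex = "male",
                                    measure = "gp_ba") {
  stopifnot(length(ca) == length(median), length(ca) >= 1)
  if (any(diff(ca) <= 0)) {
    abort("Ages must be strictly increasing.",
          class = "boneagecal_domain_error")
  }
  new_median_curve(
    tibble::tibble(sex = match_sex(sex), ca = ca, median = median,
                   n = NA_integer_),
    measure = measure, monotone = !is.unsorted(median))
}

#' Build a correction table from a median curve
#'
#' Emits the applicable form of a median-mapped GP-style scale: for each
#' grid value `g` of the observed measure from `grid_lo` up to the
#' curve's top median value in steps of `grid_step`,
#' `correction(g) = round(invert(g) - g)` to the nearest `rounding`
#' unit, so that `g + correction(g)` is the population bone age. The
#' last row carries "and above" semantics: its correction applies
#' unchanged to any observed value beyond the grid.
#'
#' @param curve a monotone `median_curve` (monotonized if not).
#' @param grid_step grid spacing in years, default 0.5.
#' @param grid_lo first grid value in years, default 2.0.
#' @param rounding rounding unit for corrections in years, default 0.1.
#' @return a tibble of class `correction_table` with columns `sex`,
#'   `gp_ba`, `correction`, `terminal`.
#' @export
build_correction_table <- function(curve, grid_step = 0.5, grid_lo = 2.0,
                                   rounding = 0.1) {
  stopifnot(inherits(curve, "median_curve"))
  if (is.unsorted(curve$median)) curve <- monotonize(curve)
  top <- max(curve$median)
  if (top < grid_lo) {
    abort("Curve's median range lies entirely below `grid_lo`; empty grid.",
          class = "boneagecal_domain_error")
  }
  grid <- seq(grid_lo, top + 1e-9, by = grid_step)
  ba <- suppressWarnings(invert_to_bone_age(curve, grid))
  corr <- round_to(as.numeric(ba) - grid, rounding)
  new_correction_table(tibble::tibble(
    sex = curve$sex[1],
    gp_ba = grid,
    correction = corr,
    terminal = seq_along(grid) == length(grid)
  ))
}

new_correction_table <- function(df) {
  structure(df, class = c("correction_table", class(tibble::tibble())))
}

#' Build an SMS anchor table (TW-style scale) from a cohort
#'
#' Median-mapping for the Tanner-Whitehouse Sum Maturity Score: the
#' monotonized median SMS at each grid age becomes an anchor pair
#' (bone age = grid age, SMS = median). The table is then truncated or
#' extended so its terminal anchor sits exactly at SMS 1000 (full
#' maturity), at the age where the fitted median first reaches 1000 by
#' linear continuation of the last segment.
#'
#' @inheritParams median_by_age
#' @param ba_grid grid of bone ages (anchor ages) in years.
#' @return a tibble of class `sms_anchor_table` with columns `sex`,
#'   `bone_age`, `sms`.
#' @export
build_sms_scale <- function(cohort, sex, ba_grid = anniversary_ages(),
                            bin_width = 1.0, n_min = 10) {
  curve <- monotonize(median_by_age(cohort, sex, measure = "sms",
                                    grid = ba_grid, bin_width = bin_width,
                                    n_min = n_min))
  anchors <- tibble::tibble(sex = curve$sex, bone_age = curve$ca,
                            sms = pmin(curve$median, 1000))
  anchors <- terminal_extend(anchors)
  new_sms_anchor_table(anchors)
}

# place the terminal anchor exactly at SMS 1000: truncate past the first
# crossing, or extend the last segment linearly if 1000 is never reached
terminal_extend <- function(anchors) {
  s <- anchors$sms
  a <- anchors$bone_age
  n <- length(s)
  if (max(s) >= 1000) {
    k <- min(which(s >= 1000))
    if (s[k] == 1000) return(anchors[seq_len(k), ])
    age_end <- a[k - 1] + (1000 - s[k - 1]) / (s[k] - s[k - 1]) *
      (a[k] - a[k - 1])
    keep <- anchors[seq_len(k - 1), ]
  } else {
    if (n < 2 || s[n] <= s[n - 1]) {
      abort("Cannot extend to SMS 1000: last segment is not increasing.",
            class = "boneagecal_calibration_error")
    }
    slope <- (s[n] - s[n - 1]) / (a[n] - a[n - 1])
    age_end <- a[n] + (1000 - s[n]) / slope
    keep <- anchors
  }
  dplyr::bind_rows(keep, tibble::tibble(sex = anchors$sex[1],
                                        bone_age = age_end, sms = 1000))
}

new_sms_anchor_table <- function(df) {
  structure(df, class = c("sms_anchor_table", class(tibble::tibble())))
}

#' End of a calibrated GP-style scale
#'
#' The population scale ends where the parent GP scale ends, shifted by
#' the terminal ("and above") correction: `gp_scale_end + terminal
#' correction`. The GP bone age scale itself terminates at 19 years for
#' boys and 18 years for girls.
#'
#' @param table a `correction_table`.
#' @param gp_scale_end end of the parent GP scale in years.
#' @return scale end in years.
#' @examples
#' scale_end(china05_corrections("male"), 19)   # 17.8
#' @export
scale_end <- function(table, gp_scale_end) {
  stopifnot(inherits(table, "correction_table"), nrow(table) >= 1)
  term <- table$correction[table$terminal]
  if (length(term) != 1) term <- table$correction[nrow(table)]
  gp_scale_end + term
}

#' One-call GP-scale calibration
#'
#' Runs the full median-mapping construction for the Greulich-Pyle
#' measure -- tabulate medians by age, monotonize, invert, emit the
#' correction table -- and returns a calibration object with the
#' intermediate curves attached. `tidy()` returns the correction table,
#' `glance()` a one-row summary, `autoplot()` the correction profile.
#'
#' @inheritParams median_by_age
#' @inheritParams build_correction_table
#' @return an object of class `ba_calibration`.
#' @export
calibrate_gp_scale <- function(cohort, sex, grid = anniversary_ages(),
                               bin_width = 1.0, n_min = 10,
                               grid_step = 0.5, grid_lo = 2.0,
                               rounding = 0.1) {
  raw <- median_by_age(cohort, sex, measure = "gp_ba", grid = grid,
                       bin_width = bin_width, n_min = n_min)
  mono <- monotonize(raw)
  table <- build_correction_table(mono, grid_step = grid_step,
                                  grid_lo = grid_lo, rounding = rounding)
  structure(list(kind = "gp", sex = match_sex(sex), median_raw = raw,
                 median_curve = mono, table = table,
                 n_records = sum(raw$n)),
            class = "ba_calibration")
}

#' One-call TW/SMS-scale calibration
#'
#' As [calibrate_gp_scale()] but for the Sum Maturity Score: the result
#' holds an SMS anchor table instead of a correction table.
#'
#' @inheritParams build_sms_scale
#' @return an object of class `ba_calibration`.
#' @export
calibrate_sms_scale <- function(cohort, sex, ba_grid = anniversary_ages(),
                                bin_width = 1.0, n_min = 10) {
  raw <- median_by_age(cohort, sex, measure = "sms", grid = ba_grid,
                       bin_width = bin_width, n_min = n_min)
  table <- build_sms_scale(cohort, sex, ba_grid = ba_grid,
                           bin_width = bin_width, n_min = n_min)
  structure(list(kind = "sms", sex = match_sex(sex), median_raw = raw,
                 median_curve = monotonize(raw), table = table,
                 n_records = sum(raw$n)),
            class = "ba_calibration")
}

#' @export
print.ba_calibration <- function(x, ...) {
  cat(sprintf("<ba_calibration> %s scale, %s, %d records\n",
              toupper(x$kind), x$sex, x$n_records))
  print(x$table)
  invisible(x)
}
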