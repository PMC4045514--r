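#' Default sampling ages of the emulated study design
#'
#' Anniversary ages 2--20 years plus the two extra sampling points at
#' 2.5 and 3.5 years.
#'
#' @return numeric vector of ages in years.
#' @export
anniversary_ages <- function() sort(c(seq(2, 20, by = 1), 2.5, 3.5))

default_offset_curves <- function() {
  list(
    # maturation advancement ramps up through puberty and plateaus near
    # +1 y at its end; girls enter and finish puberty earlier than boys
    male   = offset_curve(c(2, 8, 13, 16, 20), c(0, 0, 0.5, 1.0, 1.0)),
    female = offset_curve(c(2, 7, 12, 15, 20), c(0, 0, 0.6, 1.0, 1.0))
  )
}

default_city_shifts <- function() {
  c(Dalian = -0.3, Shijiazhuang = -0.1, Wenzhou = 0,
    Guangzhou = 0.1, Shanghai = 0.3)
}

#' Simulate an anniversary-sampled cross-sectional bone-age cohort
#'
#' Generates a cohort with the statistical structure the downstream
#' calibration assumes: children sampled near their anniversaries in
#' several cities, a sex-specific population maturation-offset curve
#' (mean BA - CA as a function of age), additive city shifts, and
#' Gaussian individual variation around the population mean. For each
#' sex, sampling age, city and replicate the generator draws
#'
#' \deqn{ca = a + jitter, \quad gp\_ba = ca + offset_{sex}(ca) +
#'   shift_{city} + \epsilon, \quad \epsilon \sim N(0, residual\_sd)}
#'
#' An SMS score is produced by pushing an independently noised TW-scale
#' bone age (same offset structure) through [maturity_to_sms()], so the
#' GP and TW calibrations remain distinct measurements. Optionally a
#' manual TW3 re-rating is emulated as the automated rating minus a
#' sex-specific rater difference `N(rater_bias, rater_sd)`, giving
#' realistic input for Bland-Altman agreement analysis.
#'
#' @param n_per_age replicates per sex x age x city combination.
#' @param ages sampling ages in years; default [anniversary_ages()].
#' @param cities named numeric vector: city label -> additive BA shift
#'   in years. A single unnamed 0 gives a one-city cohort.
#' @param offset_curve_male,offset_curve_female [offset_curve()]
#'   functions giving mean BA - CA versus age per sex.
#' @param residual_sd SD in years of individual BA - CA variation.
#' @param age_jitter_sd SD in years of sampling around each anniversary.
#' @param rater_bias,rater_sd named vectors (`male`, `female`): mean and
#'   SD in years of the automated-minus-manual TW3 rating difference.
#' @param simulate_rater if `FALSE`, skip the `tw3_*` columns.
#' @param seed integer seed; the same seed reproduces the cohort
#'   exactly. The caller's RNG state is left untouched.
#' @return a `ba_cohort` tibble (see [as_cohort()]).
#' @examples
#' coh <- simulate_cohort(n_per_age = 2, seed = 1)
#' dplyr::count(coh, sex)
#' @export
simulate_cohort <- function(n_per_age = 25,
                            ages = anniversary_ages(),
                            cities = default_city_shifts(),
                            offset_curve_male = default_offset_curves()$male,
                            offset_curve_female = default_offset_curves()$female,
                            residual_sd = 1.1,
                            age_jitter_sd = 0.05,
                            rater_bias = c(male = 0.00, female = -0.37),
                            rater_sd = c(male = 0.64, female = 0.57),
                            simulate_rater = TRUE,
                            seed = NULL) {
  if (n_per_age < 1) abort("`n_per_age` must be at least 1.",
                           class = "boneagecal_config_error")
  if (residual_sd <= 0) abort("`residual_sd` must be positive.",
                              class = "boneagecal_config_error")
  if (any(ages <= 0)) abort("All sampling ages must be positive.",
                            class = "boneagecal_config_error")
  if (age_jitter_sd < 0) abort("`age_jitter_sd` must be non-negative.",
                               class = "boneagecal_config_error")
  if (is.null(names(cities))) {
    if (length(cities) != 1) abort("`cities` must be a named vector.",
                                   class = "boneagecal_config_error")
    names(cities) <- "city1"
  }

  local_seed(seed)
  curves <- list(male = offset_curve_male, female = offset_curve_female)

  grid <- tidyr::expand_grid(
    sex = SEX_LEVELS,
    age = sort(ages),
    city = names(cities),
    rep = seq_len(n_per_age)
  )
  n <- nrow(grid)
  ca <- pmax(grid$age + rnorm(n, 0, age_jitter_sd), 0.1)
  offset <- numeric(n)
  for (s in SEX_LEVELS) {
    idx <- grid$sex == s
    offset[idx] <- curves[[s]](ca[idx])
  }
  shift <- unname(cities[grid$city])
  gp_ba <- pmax(ca + offset + shift + rnorm(n, 0, residual_sd), 0.1)
  tw_ba <- pmax(ca + offset + shift + rnorm(n, 0, residual_sd), 0.1)
  sms <- numeric(n)
  for (s in SEX_LEVELS) {
    idx <- grid$sex == s
    sms[idx] <- round(maturity_to_sms(tw_ba[idx], s))
  }

  out <- tibble::tibble(
    subject_id = sprintf("sim%05d", seq_len(n)),
    sex = grid$sex,
    city = grid$city,
    ca = ca,
    gp_ba = gp_ba,
    sms = sms
  )
  if (simulate_rater) {
    diff <- numeric(n)
    for (s in SEX_LEVELS) {
      idx <- grid$sex == s
      diff[idx] <- rnorm(sum(idx), rater_bias[[s]], rater_sd[[s]])
    }
    out$tw3_auto <- tw_ba
    out$tw3_manual <- tw_ba - diff
  }
  as_cohort(out, provenance = sprintf(
    "simulate_cohort(n_per_age=%d, cities=%d, residual_sd=%g, seed=%s)",
    n_per_age, length(cities), residual_sd,
    if (is.null(seed)) "NULL" else seed))
}

#' Map a TW-scale bone age to a Sum Maturity Score
#'
#' Strictly increasing piecewise-linear map through an anchor set of
#' (bone age, SMS) pairs, by default the packaged TW-China05 anchors, so
#' the generator and the published scale are mutually consistent. Output
#' is clamped to the first anchor's SMS below the anchor range and to
#' 1000 (full maturity) at or beyond the terminal anchor age.
#'
#' @param tw_ba TW-scale bone age(s) in years; must be positive.
#' @param sex `"male"` or `"female"`.
#' @param anchors an `sms_anchor_table` (see [china05_sms_anchors()]).
#' @return numeric SMS score(s) in \[0, 1000\].
#' @examples
#' maturity_to_sms(10, "male")   # 296, an exact anchor
#' @export
maturity_to_sms <- function(tw_ba, sex, anchors = china05_sms_anchors()) {
  if (any(tw_ba <= 0)) abort("TW bone age must be positive.",
                             class = "boneagecal_domain_error")
  sex <- match_sex(sex)
  a <- dplyr::filter(tibble::as_tibble(anchors), .data$sex == .env$sex)
  approx(a$bone_age, a$sms, xout = tw_ba, rule = 2)$y
}

# run the rest of the caller under a fixed seed without disturbing the
# caller's RNG stream; NULL leaves the ambient stream in place
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_preserve_seed(.local_envir = envir)
    set.seed(seed)
  }
  invisible()
}
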