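test_that("a noise-free constant offset gives flat mean and zero SD in every bin", {
  coh <- noise_free_cohort(function(ca) 0.5)
  curve <- ba_minus_ca_curve(coh, "male")
  expect_equal(curve$mean_diff, rep(0.5, nrow(curve)))
  expect_equal(curve$sd_diff, rep(0, nrow(curve)))
  expect_equal(sum(curve$n), nrow(coh))
})

test_that("per-bin mean and SD agree with a brute-force recomputation", {
  coh <- simulate_cohort(n_per_age = 30, seed = 8)
  curve <- ba_minus_ca_curve(coh, "female", n_min = 5)
  raw <- as.data.frame(coh)[coh$sex == "female" & !is.na(coh$gp_ba), ]
  for (k in seq_len(nrow(curve))) {
    ctr <- curve$bin_center[k]
    vals <- raw$gp_ba[raw$ca >= ctr - 0.5 & raw$ca < ctr + 0.5] -
      raw$ca[raw$ca >= ctr - 0.5 & raw$ca < ctr + 0.5]
    expect_equal(curve$n[k], length(vals))
    expect_equal(curve$mean_diff[k], mean(vals))
    expect_equal(curve$sd_diff[k], sd(vals))
  }
})

test_that("bins below the n_min threshold are absent, not zero-filled", {
  coh <- noise_free_cohort(ages = c(5, 6), n_per_age = 10)
  # thin out the 6-year bin to n_min - 1
  thin <- as_cohort(as.data.frame(coh)[-(which(coh$ca == 6)[1]), ])
  curve <- ba_minus_ca_curve(thin, "male", n_min = 10)
  expect_identical(curve$bin_center, 5)
  expect_error(ba_minus_ca_curve(thin, "female", n_min = 10),
               class = "boneagecal_empty_curve_error")
})

test_that("per-bin SD recovers the generator's residual SD (Monte Carlo)", {
  # SE of a sample SD is sigma / sqrt(2n) ~ 0.02 at n = 2000
  coh <- simulate_cohort(
    n_per_age = 2000, ages = c(9, 13), cities = c(only = 0),
    offset_curve_male = constant_offset(0),
    offset_curve_female = constant_offset(0),
    residual_sd = 1.26, seed = 31, simulate_rater = FALSE)
  curve <- ba_minus_ca_curve(coh, "male")
  expect_true(all(abs(curve$sd_diff - 1.26) < 0.08))
})

test_that("average_sd is the unweighted mean of in-range bin SDs", {
  curve <- structure(
    tibble::tibble(sex = "male", bin_center = c(7, 8, 9),
                   mean_diff = 0, sd_diff = c(1.0, 1.2, 1.4), n = 50L),
    class = c("binned_curve", class(tibble::tibble())))
  expect_equal(average_sd(curve, 7, 9), 1.2)
  expect_equal(average_sd(curve, 8, 8), 1.2)  # single bin
  constant <- dplyr::mutate(curve, sd_diff = 1.12)
  expect_equal(average_sd(constant, 7, 9), 1.12)
  expect_error(average_sd(curve, 20, 25), class = "boneagecal_domain_error")
})

test_that("noise-free city shifts separate the city curves exactly", {
  coh <- noise_free_cohort(cities = c(north = -0.3, south = 0.3))
  curves <- city_curves(coh, "male")
  wide <- tidyr::pivot_wider(tibble::as_tibble(curves),
                             id_cols = "bin_center",
                             names_from = "city",
                             values_from = "mean_diff")
  expect_equal(wide$south - wide$north, rep(0.6, nrow(wide)))
})

test_that("a single-city cohort's city curve equals the overall curve", {
  coh <- simulate_cohort(n_per_age = 20, cities = c(solo = 0.1), seed = 3)
  per_city <- city_curves(coh, "male")
  overall <- ba_minus_ca_curve(coh, "male")
  expect_equal(unique(per_city$city), "solo")
  expect_equal(per_city$mean_diff, overall$mean_diff)
  expect_equal(per_city$n, overall$n)
})

test_that("city curves pooled by n reproduce the overall mean curve", {
  coh <- simulate_cohort(n_per_age = 40, seed = 17)
  per_city <- tibble::as_tibble(city_curves(coh, "female", n_min = 1))
  overall <- ba_minus_ca_curve(coh, "female", n_min = 1)
  pooled <- per_city |>
    dplyr::group_by(bin_center) |>
    dplyr::summarise(mean_diff = sum(mean_diff * n) / sum(n),
                     n = sum(n), .groups = "drop")
  merged <- dplyr::inner_join(pooled, tibble::as_tibble(overall),
                              by = "bin_center")
  expect_equal(merged$mean_diff.x, merged$mean_diff.y, tolerance = 1e-9)
  expect_equal(merged$n.x, merged$n.y)
})

test_that("five injected city shifts are recovered in rank order", {
  shifts <- c(a = -0.3, b = -0.15, c = 0, d = 0.15, e = 0.3)
  coh <- simulate_cohort(
    n_per_age = 100, cities = shifts,
    offset_curve_male = constant_offset(0),
    offset_curve_female = constant_offset(0),
    residual_sd = 1.1, seed = 23, simulate_rater = FALSE)
  per_city <- tibble::as_tibble(city_curves(coh, "male")) |>
    dplyr::group_by(city) |>
    dplyr::summarise(shift = sum(mean_diff * n) / sum(n))
  recovered <- per_city$shift[match(names(shifts), per_city$city)]
  expect_identical(order(recovered), order(shifts))
})

test_that("a cohort with no city labels cannot be split by city", {
  coh <- noise_free_cohort()
  coh$city <- NA_character_
  expect_error(city_curves(coh, "male"), class = "boneagecal_domain_error")
})
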