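test_that("median_by_age uses the interpolated sample median per bin", {
  df <- data.frame(
    subject_id = as.character(1:7), sex = "male",
    ca = c(5, 5.1, 4.9, 6, 6.1, 5.9, 6.2),
    gp_ba = c(1, 2, 3, 1, 2, 3, 4))
  coh <- as_cohort(df)
  mc <- median_by_age(coh, "male", grid = c(5, 6), n_min = 3)
  expect_equal(mc$median, c(2, 2.5))  # odd bin -> 2, even bin -> 2.5
  expect_equal(mc$n, c(3L, 4L))
})

test_that("grid ages failing n_min are dropped with a warning; < 2 survivors is an error", {
  coh <- noise_free_cohort(ages = c(5, 6, 7), n_per_age = 10)
  expect_warning(
    mc <- median_by_age(coh, "male", grid = c(5, 6, 7, 12), n_min = 10),
    "Dropping")
  expect_equal(mc$ca, c(5, 6, 7))
  expect_error(
    suppressWarnings(median_by_age(coh, "male", grid = c(5, 12), n_min = 10)),
    class = "boneagecal_calibration_error")
})

test_that("monotonize applies pool-adjacent-violators and is the identity on monotone input", {
  wiggly <- median_curve_from_pairs(10:12, c(5.0, 4.8, 5.2))
  fixed <- monotonize(wiggly)
  expect_equal(fixed$median, c(4.9, 4.9, 5.2))  # PAV pools the violator pair

  mono <- median_curve_from_pairs(10:13, c(5, 6, 7, 8))
  expect_equal(monotonize(mono)$median, mono$median)

  flat <- median_curve_from_pairs(10:12, c(5, 5, 5))
  expect_equal(monotonize(flat)$median, flat$median)
})

test_that("inversion reproduces the defining worked example", {
  # median GP BA 13.5 at CA 13 => a GP BA of 13.5 maps to bone age 13.0
  mc <- median_curve_from_pairs(12:14, c(12.4, 13.5, 14.6))
  expect_equal(as.numeric(invert_to_bone_age(mc, 13.5)), 13.0)
})

test_that("inversion interpolates linearly and is the identity on the identity curve", {
  mc <- median_curve_from_pairs(c(12, 13), c(12.4, 13.6))
  expect_equal(as.numeric(invert_to_bone_age(mc, 13.0)), 12.5)

  ident <- median_curve_from_pairs(2:20, 2:20)
  x <- seq(2.3, 19.7, by = 0.37)
  expect_equal(as.numeric(invert_to_bone_age(ident, x)), x)
})

test_that("flat segments invert to the midpoint of the tied age range", {
  mc <- median_curve_from_pairs(10:14, c(5, 6, 6, 6, 7))
  expect_equal(as.numeric(invert_to_bone_age(mc, 6)), 12)  # mid of 11..13
  expect_equal(as.numeric(invert_to_bone_age(mc, 5)), 10)  # single hit
})

test_that("out-of-range observations clamp to the grid ends with a flag", {
  mc <- median_curve_from_pairs(5:8, c(5.5, 6.5, 7.5, 8.5))
  expect_warning(lo <- invert_to_bone_age(mc, 4.0), "clamped")
  expect_equal(as.numeric(lo), 5)
  expect_true(attr(lo, "out_of_range"))
  expect_warning(hi <- invert_to_bone_age(mc, 9.9), "clamped")
  expect_equal(as.numeric(hi), 8)
})

test_that("an identity median curve yields an all-zero correction table", {
  mc <- median_curve_from_pairs(2:20, 2:20)
  tab <- build_correction_table(mc)
  expect_equal(tab$correction, rep(0, nrow(tab)))
  expect_equal(tab$gp_ba, seq(2, 20, by = 0.5))
  expect_true(tab$terminal[nrow(tab)])
  expect_false(any(tab$terminal[-nrow(tab)]))
})

test_that("a late-onset offset produces near-zero early and ~-1 terminal corrections", {
  # population runs +1 y advanced only above CA 14
  off <- function(ca) approx(c(2, 14, 15, 20), c(0, 0, 1, 1),
                             xout = ca, rule = 2)$y
  mc <- median_curve_from_pairs(2:20, 2:20 + off(2:20))
  tab <- build_correction_table(mc)
  early <- tab$correction[tab$gp_ba <= 13.5]
  late <- tab$correction[tab$gp_ba >= 17]
  expect_true(all(abs(early) < 1e-9))
  expect_true(all(abs(late + 1.0) < 1e-9))
})

test_that("pre-rounding, g + correction(g) equals the inverted bone age exactly", {
  set.seed(4)
  med <- cumsum(runif(19, 0.2, 1.6)) + 1
  mc <- monotonize(median_curve_from_pairs(2:20, med))
  tab <- build_correction_table(mc, rounding = 1e-12)
  expect_equal(tab$gp_ba + tab$correction,
               as.numeric(suppressWarnings(
                 invert_to_bone_age(mc, tab$gp_ba))),
               tolerance = 1e-9)
})

test_that("the calibrated scale g + correction(g) is monotone non-decreasing", {
  set.seed(9)
  for (rep in 1:5) {
    med <- cumsum(runif(19, 0.1, 1.8)) + 1.5
    mc <- monotonize(median_curve_from_pairs(2:20, med))
    tab <- build_correction_table(mc)
    # post-rounding: non-decreasing within one rounding unit
    expect_true(all(diff(tab$gp_ba + tab$correction) >= -0.1 - 1e-9))
    pre <- build_correction_table(mc, rounding = 1e-12)
    expect_true(all(diff(pre$gp_ba + pre$correction) >= -1e-9))
  }
})

test_that("build_sms_scale recovers published anchors from a noise-free cohort", {
  anchors <- china05_sms_anchors("male")
  coh <- noise_free_cohort(
    ages = 2:16, n_per_age = 12,
    sms_fun = function(ca) maturity_to_sms(ca, "male"))
  tab <- build_sms_scale(coh, "male", ba_grid = 2:16)
  ref <- anchors[anchors$bone_age %in% 2:16, ]
  inner <- tab[tab$sms < 1000, ]
  expect_equal(inner$bone_age, ref$bone_age)
  expect_equal(inner$sms, ref$sms)
  # terminal anchor extended to exactly SMS 1000
  expect_equal(tab$sms[nrow(tab)], 1000)
})

test_that("the terminal anchor extends the last segment linearly to SMS 1000", {
  coh <- noise_free_cohort(
    ages = c(15, 16), n_per_age = 12,
    sms_fun = function(ca) approx(c(15, 16), c(835, 959), ca, rule = 2)$y)
  tab <- build_sms_scale(coh, "male", ba_grid = c(15, 16), n_min = 5)
  expect_equal(tab$bone_age[nrow(tab)], 16 + 41 / 124, tolerance = 1e-9)
  expect_equal(tab$sms[nrow(tab)], 1000)
})

test_that("scale_end adds the terminal correction to the parent scale end", {
  expect_equal(scale_end(china05_corrections("male"), 19), 17.8)
  expect_equal(scale_end(china05_corrections("female"), 18), 16.8)
  zero <- build_correction_table(median_curve_from_pairs(2:20, 2:20))
  expect_equal(scale_end(zero, 19), 19)
})

test_that("calibration on a known offset recovers correction = -offset(inverted age)", {
  # 3x the median SE: 1.2533 * 1.1 / sqrt(1000) ~ 0.044, plus 0.05 rounding
  off <- offset_curve(c(2, 8, 13, 16, 20), c(0, 0, 0.5, 1.0, 1.0))
  coh <- simulate_cohort(
    n_per_age = 1000, cities = c(only = 0),
    offset_curve_male = off, offset_curve_female = off,
    residual_sd = 1.1, seed = 61, simulate_rater = FALSE)
  cal <- calibrate_gp_scale(coh, "male")
  tab <- cal$table
  # truth: correction(g) = -offset at the age where the true median = g
  true_med <- function(ca) ca + off(ca)
  inv_true <- function(g) approx(true_med(seq(2, 20, 0.01)),
                                 seq(2, 20, 0.01), xout = g)$y
  interior <- tab$gp_ba > 2.5 & tab$gp_ba < max(true_med(19.5))
  expected <- -off(inv_true(tab$gp_ba[interior]))
  expect_true(all(abs(tab$correction[interior] - expected) <= 0.15))
})

test_that("tidy and glance expose the calibrated table and its summary", {
  coh <- simulate_cohort(n_per_age = 60, cities = c(only = 0), seed = 14,
                         simulate_rater = FALSE)
  cal <- calibrate_gp_scale(coh, "female")
  expect_s3_class(tidy(cal), "tbl_df")
  expect_named(tidy(cal), c("sex", "gp_ba", "correction", "terminal"))
  g <- glance(cal)
  expect_identical(nrow(g), 1L)
  expect_equal(g$scale_end, 18 + g$terminal_correction)
  sms <- calibrate_sms_scale(coh, "female")
  expect_equal(glance(sms)$scale_end, sms$table$bone_age[nrow(sms$table)])
  expect_equal(tidy(sms)$sms[nrow(tidy(sms))], 1000)
})
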