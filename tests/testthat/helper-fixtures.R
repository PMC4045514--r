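# deterministic cohort builders used across the suite

# noise-free cohort: every record sits exactly on its anniversary and
# gp_ba = ca + offset(ca) + city shift, with no individual variation
noise_free_cohort <- function(offset_fun = function(ca) 0,
                              ages = seq(2, 20, by = 1),
                              n_per_age = 12,
                              sex = "male",
                              cities = c(city1 = 0),
                              sms_fun = NULL) {
  grid <- expand.grid(age = ages, city = names(cities),
                      rep = seq_len(n_per_age),
                      stringsAsFactors = FALSE)
  ca <- grid$age
  gp <- ca + offset_fun(ca) + unname(cities[grid$city])
  df <- data.frame(
    subject_id = sprintf("nf%04d", seq_len(nrow(grid))),
    sex = sex, city = grid$city, ca = ca, gp_ba = gp
  )
  if (!is.null(sms_fun)) df$sms <- sms_fun(ca)
  as_cohort(df, provenance = "noise-free fixture")
}

# a small fully-populated cohort for I/O tests
tiny_cohort <- function() {
  as_cohort(data.frame(
    subject_id = c("a", "b", "c"),
    sex = c("male", "female", "F"),
    city = c("X", "Y", ""),
    ca = c(9.02, 10.5, 3.25),
    gp_ba = c(9.5, 10.1, NA),
    sms = c(262, 496, NA),
    tw3_manual = c(9.4, NA, 3.1),
    tw3_auto = c(9.6, NA, 3.3)
  ))
}

expect_cohorts_equal <- function(a, b) {
  expect_identical(nrow(a), nrow(b))
  for (col in c("subject_id", "sex", "city")) {
    expect_identical(a[[col]], b[[col]], label = col)
  }
  for (col in c("ca", "gp_ba", "sms", "tw3_manual", "tw3_auto")) {
    expect_identical(unname(a[[col]]), unname(b[[col]]), label = col)
  }
}
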