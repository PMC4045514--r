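# cache for the packaged scale tables (parsed once per session)
the <- new.env(parent = emptyenv())

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "boneagecal")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install
  path
}

#' Packaged BX-China05 correction table
#'
#' The published correction table adapting Greulich-Pyle bone age to
#' Chinese children (2005 reference cohort): a grid of GP bone ages
#' from 2.0 to 17.0 years in 0.5-year steps with the additive
#' correction in years for each sex, the last row applying to 17.0
#' years "and above". `BX-China05 = GP BA + correction`.
#'
#' @param sex `"male"` or `"female"`.
#' @return a `correction_table` tibble (columns `sex`, `gp_ba`,
#'   `correction`, `terminal`).
#' @examples
#' china05_corrections("female")
#' @export
china05_corrections <- function(sex) {
  sex <- match_sex(sex)
  if (is.null(the$bx)) {
    the$bx <- readr::read_csv(pkg_extdata("bx_china05_corrections.csv"),
                              col_types = "dddl", progress = FALSE)
  }
  wide <- the$bx
  col <- if (sex == "male") "correction_boys" else "correction_girls"
  new_correction_table(tibble::tibble(
    sex = sex, gp_ba = wide$gp_ba, correction = wide[[col]],
    terminal = wide$terminal))
}

#' Packaged TW-China05 SMS anchor table
#'
#' The published correspondence between TW-China05 bone age and the
#' Tanner-Whitehouse Sum Maturity Score, per sex. Anchors are strictly
#' increasing in both coordinates; the terminal anchor sits at SMS 1000
#' (full maturity), reached at 16.1 years for boys and 15.1 years for
#' girls.
#'
#' @param sex `"male"`, `"female"`, or `NULL` for both sexes.
#' @return an `sms_anchor_table` tibble (columns `sex`, `bone_age`,
#'   `sms`).
#' @export
china05_sms_anchors <- function(sex = NULL) {
  if (is.null(the$tw)) {
    the$tw <- readr::read_csv(pkg_extdata("tw_china05_anchors.csv"),
                              col_types = "cdd", progress = FALSE)
  }
  out <- the$tw
  if (!is.null(sex)) {
    sex <- match_sex(sex)
    out <- dplyr::filter(out, .data$sex == .env$sex)
  }
  new_sms_anchor_table(out)
}

#' Apply a BX-style correction table to Greulich-Pyle bone ages
#'
#' Translates an observed GP bone age onto the population-adapted scale
#' by adding the tabulated correction: exact grid hits use the printed
#' correction, values between grid points interpolate linearly between
#' the adjacent corrections, values beyond the terminal grid row keep
#' the terminal ("and above") correction unchanged, and values below
#' the first grid row keep the first correction, with a warning. With
#' the packaged table: a girl with GP BA 10.0 has BX-China05
#' 10.0 - 0.1 = 9.9 years.
#'
#' Outputs beyond the automated method's reliability limits (GP BA 17
#' years for boys, 15 for girls, i.e. 15.8 / 13.8 on the adapted scale)
#' carry increased uncertainty; a warning flags them when
#' `warn_limits = TRUE`.
#'
#' @param gp_ba Greulich-Pyle bone age(s) in years; must be positive.
#' @param sex `"male"` or `"female"`.
#' @param table a `correction_table`; default the packaged BX-China05
#'   table for `sex`.
#' @param warn_limits warn when `gp_ba` exceeds the reliability limit.
#' @return adapted bone age(s) in years.
#' @examples
#' bx_china05(10.0, "female")   # 9.9
#' bx_china05(12.0, "female")   # 11.5
#' @export
bx_china05 <- function(gp_ba, sex, table = NULL, warn_limits = TRUE) {
  if (any(is.na(gp_ba)) || any(gp_ba <= 0)) {
    abort("GP bone age must be positive.", class = "boneagecal_domain_error")
  }
  sex <- match_sex(sex)
  table <- table %||% china05_corrections(sex)
  stopifnot(inherits(table, "correction_table"))
  below <- gp_ba < min(table$gp_ba)
  if (any(below)) {
    warn(sprintf("%d GP BA value(s) below the table grid; first-row correction applied.",
                 sum(below)))
  }
  if (warn_limits) {
    limit <- if (sex == "male") 17 else 15
    if (any(gp_ba > limit)) {
      warn(sprintf("%d GP BA value(s) above the %g-year reliability limit for %ss; adapted bone ages are increasingly uncertain there.",
                   sum(gp_ba > limit), limit, sex))
    }
  }
  corr <- if (nrow(table) == 1) rep(table$correction, length(gp_ba)) else
    approx(table$gp_ba, table$correction, xout = gp_ba, rule = 2)$y
  gp_ba + corr
}

#' Apply a TW-style SMS anchor table to Sum Maturity Scores
#'
#' Converts an observed SMS to the population-adapted TW-style bone age
#' by piecewise-linear interpolation on the (SMS, bone age) anchor
#' pairs; exact anchor hits return the anchored bone age. SMS values
#' below the first anchor clamp to the first anchored bone age with a
#' warning; SMS outside \[0, 1000\] is an error. With the packaged
#' table: a boy with SMS 296 has TW-China05 = 10.0 years, and SMS 1000
#' maps to the scale ends of 16.1 (boys) and 15.1 (girls) years.
#'
#' @param sms Sum Maturity Score(s) in \[0, 1000\].
#' @param sex `"male"` or `"female"`.
#' @param table an `sms_anchor_table`; default the packaged TW-China05
#'   anchors for `sex`.
#' @return adapted bone age(s) in years.
#' @examples
#' tw_china05(296, "male")    # 10.0
#' tw_china05(1000, "female") # 15.1
#' @export
tw_china05 <- function(sms, sex, table = NULL) {
  if (any(is.na(sms)) || any(sms < 0 | sms > 1000)) {
    abort("SMS must lie in [0, 1000].", class = "boneagecal_domain_error")
  }
  sex <- match_sex(sex)
  table <- table %||% china05_sms_anchors(sex)
  stopifnot(inherits(table, "sms_anchor_table"))
  anch <- dplyr::filter(tibble::as_tibble(table), .data$sex == .env$sex)
  if (nrow(anch) < 2) {
    abort(sprintf("Anchor table has no usable anchors for sex \"%s\".", sex),
          class = "boneagecal_domain_error")
  }
  below <- sms < min(anch$sms)
  if (any(below)) {
    warn(sprintf("%d SMS value(s) below the first anchor; clamped to the first anchored bone age.",
                 sum(below)))
  }
  approx(anch$sms, anch$bone_age, xout = sms, rule = 2)$y
}

#' Read a scale table from CSV, enforcing its invariants
#'
#' Two layouts are recognized. Correction tables: either long
#' (`sex, gp_ba, correction, terminal`) or wide
#' (`gp_ba, correction_boys, correction_girls, terminal`), grid strictly
#' increasing, corrections exact multiples of `rounding` when
#' `strict = TRUE`, and `gp_ba + correction` non-decreasing. SMS anchor
#' tables: `sex, bone_age, sms`, both coordinates strictly increasing
#' within sex, SMS within \[0, 1000\] with the terminal anchor exactly
#' 1000. Violations raise an error naming the first offending row.
#'
#' @param path CSV file.
#' @param kind `"correction"` or `"sms"`.
#' @param sex for wide correction files, which sex's column to extract;
#'   ignored for long layouts (default: keep all rows).
#' @param strict enforce the rounding-unit invariant on corrections.
#' @param rounding rounding unit in years, default 0.1.
#' @return a `correction_table` or `sms_anchor_table`.
#' @export
load_scale <- function(path, kind = c("correction", "sms"), sex = NULL,
                       strict = TRUE, rounding = 0.1) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("Scale file does not exist: %s", path),
          class = "boneagecal_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (kind == "correction") {
    if (all(c("correction_boys", "correction_girls") %in% names(df))) {
      long <- dplyr::bind_rows(
        tibble::tibble(sex = "male", gp_ba = df$gp_ba,
                       correction = df$correction_boys),
        tibble::tibble(sex = "female", gp_ba = df$gp_ba,
                       correction = df$correction_girls))
      long$terminal <- rep(df$terminal %||%
                             (seq_len(nrow(df)) == nrow(df)), 2)
    } else if (all(c("sex", "gp_ba", "correction") %in% names(df))) {
      long <- df
      if (is.null(long$terminal)) {
        long <- dplyr::group_by(long, .data$sex) |>
          dplyr::mutate(terminal = dplyr::row_number() == dplyr::n()) |>
          dplyr::ungroup()
      }
    } else {
      abort("Unrecognized correction-table layout.",
            class = "boneagecal_format_error")
    }
    long$sex <- normalize_sex(long$sex)
    if (!is.null(sex)) {
      long <- dplyr::filter(long, .data$sex == match_sex(.env$sex))
    }
    validate_correction_rows(long, strict = strict, rounding = rounding)
    new_correction_table(tibble::as_tibble(long))
  } else {
    need <- c("sex", "bone_age", "sms")
    if (!all(need %in% names(df))) {
      abort("SMS anchor table must have columns sex, bone_age, sms.",
            class = "boneagecal_format_error")
    }
    df$sex <- normalize_sex(df$sex)
    if (!is.null(sex)) df <- dplyr::filter(df, .data$sex == match_sex(.env$sex))
    validate_sms_rows(df)
    new_sms_anchor_table(tibble::as_tibble(df))
  }
}

validate_correction_rows <- function(long, strict, rounding) {
  for (s in unique(long$sex)) {
    g <- dplyr::filter(long, .data$sex == .env$s)
    if (any(diff(g$gp_ba) <= 0)) {
      abort(sprintf("Correction grid not strictly increasing for %s (row %d).",
                    s, which(diff(g$gp_ba) <= 0)[1] + 1),
            class = "boneagecal_validation_error")
    }
    adapted <- g$gp_ba + g$correction
    if (any(diff(adapted) < -1e-9)) {
      abort(sprintf("gp_ba + correction decreases for %s (row %d).",
                    s, which(diff(adapted) < -1e-9)[1] + 1),
            class = "boneagecal_validation_error")
    }
    if (strict) {
      off <- abs(g$correction / rounding - round(g$correction / rounding))
      if (any(off > 1e-6)) {
        abort(sprintf("Correction not a multiple of %g for %s (row %d).",
                      rounding, s, which(off > 1e-6)[1]),
              class = "boneagecal_validation_error")
      }
    }
  }
  invisible(long)
}

validate_sms_rows <- function(df) {
  if (any(df$sms < 0 | df$sms > 1000)) {
    abort(sprintf("SMS outside [0, 1000] (row %d).",
                  which(df$sms < 0 | df$sms > 1000)[1]),
          class = "boneagecal_validation_error")
  }
  for (s in unique(df$sex)) {
    g <- dplyr::filter(df, .data$sex == .env$s)
    if (any(diff(g$bone_age) <= 0) || any(diff(g$sms) <= 0)) {
      abort(sprintf("Anchors not strictly increasing for %s.", s),
            class = "boneagecal_validation_error")
    }
    if (g$sms[nrow(g)] != 1000) {
      abort(sprintf("Terminal anchor for %s is %g, not 1000.",
                    s, g$sms[nrow(g)]),
            class = "boneagecal_validation_error")
    }
  }
  invisible(df)
}

#' Write a scale table to CSV
#'
#' Inverse of [load_scale()]: correction tables are written in the long
#' layout (`sex, gp_ba, correction, terminal`), SMS anchor tables as
#' (`sex, bone_age, sms`).
#'
#' @param table a `correction_table` or `sms_anchor_table`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_scale <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
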