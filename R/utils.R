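SEX_LEVELS <- c("male", "female")

#' Normalize sex labels
#'
#' Accepts `"male"`/`"female"` (any case) and the single-letter codes
#' `"M"`/`"F"`; anything else is an error. `NA` stays `NA`.
#'
#' @param x character vector of sex tokens.
#' @return character vector with values `"male"` or `"female"`.
#' @keywords internal
normalize_sex <- function(x) {
  token <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    token %in% c("male", "m") ~ "male",
    token %in% c("female", "f") ~ "female",
    is.na(token) | token == "" ~ NA_character_,
    TRUE ~ "invalid"
  )
  bad <- which(out == "invalid")
  if (length(bad) > 0) {
    abort(sprintf(
      "Unrecognized sex token(s): %s (row %s). Accepted: male/female/M/F.",
      paste(unique(x[bad]), collapse = ", "),
      paste(head(bad, 5), collapse = ", ")
    ), class = "boneagecal_sex_error")
  }
  out
}

match_sex <- function(sex) {
  sex <- normalize_sex(sex)
  if (length(sex) != 1 || is.na(sex)) {
    abort("`sex` must be a single value, one of \"male\" or \"female\".")
  }
  sex
}

# round to a multiple of `unit` (e.g. 0.1 years, the printed precision of
# published correction tables); guards against binary-representation drift
round_to <- function(x, unit) round(x / unit) * unit

`%||%` <- function(a, b) if (is.null(a)) b else a
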