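COHORT_COLUMNS <- c("subject_id", "sex", "city", "ca",
                    "gp_ba", "sms", "tw3_manual", "tw3_auto")
COHORT_MANDATORY <- c("subject_id", "sex", "ca")

#' Build a validated rated-radiograph cohort
#'
#' A cohort is a tibble with one row per rated radiograph. Mandatory
#' columns are `subject_id`, `sex` and `ca` (chronological age in decimal
#' years); optional rating columns are `city`, `gp_ba` (Greulich-Pyle
#' bone age, years), `sms` (Tanner-Whitehouse Sum Maturity Score,
#' 0--1000), `tw3_manual` and `tw3_auto` (TW3 bone ages, years). Missing
#' optional values are `NA`, never sentinel numbers. Subject ids need not
#' be unique: in an anniversary-sampled cross-sectional design a subject
#' may contribute radiographs at several ages.
#'
#' @param x data frame with at least the mandatory columns.
#' @param provenance free-text origin of the records (file path,
#'   generator configuration, ...), stored as an attribute.
#' @return a tibble of class `ba_cohort` with all eight cohort columns
#'   (absent optional columns filled with `NA`).
#' @examples
#' as_cohort(data.frame(subject_id = "s1", sex = "F", ca = 9.0, gp_ba = 9.4))
#' @export
as_cohort <- function(x, provenance = "in-memory") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(COHORT_MANDATORY, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort is missing mandatory column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "boneagecal_format_error")
  }
  out <- tibble::as_tibble(x)
  for (col in setdiff(COHORT_COLUMNS, names(out))) {
    out[[col]] <- if (col == "city") NA_character_ else NA_real_
  }
  out <- dplyr::select(out, dplyr::all_of(COHORT_COLUMNS), dplyr::everything())
  out$subject_id <- as.character(out$subject_id)
  out$sex <- normalize_sex(out$sex)
  # empty city labels are absent values, not a distinct city
  out$city <- dplyr::na_if(as.character(out$city), "")
  for (col in c("ca", "gp_ba", "sms", "tw3_manual", "tw3_auto")) {
    if (!is.numeric(out[[col]])) {
      suppressWarnings(num <- as.numeric(out[[col]]))
      newly_bad <- which(is.na(num) & !is.na(out[[col]]) &
                           trimws(as.character(out[[col]])) != "")
      if (col == "ca" && length(newly_bad) > 0) {
        abort(sprintf("Non-numeric chronological age (row %s).",
                      paste(head(newly_bad, 5), collapse = ", ")),
              class = "boneagecal_row_error")
      }
      out[[col]] <- num
    }
  }
  validate_cohort(out)
  attr(out, "provenance") <- provenance
  class(out) <- c("ba_cohort", class(tibble::tibble()))
  out
}

#' Validate cohort invariants
#'
#' Checks the row-level invariants of a cohort: positive chronological
#' age, positive Greulich-Pyle bone age where present, sex one of
#' male/female, and SMS within \[0, 1000\] (the score saturates at 1000
#' at full skeletal maturity). Errors name the offending rows.
#'
#' @param cohort data frame in cohort layout.
#' @return the input, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  fail <- function(rows, msg) {
    abort(sprintf("%s (row %s).", msg, paste(head(rows, 5), collapse = ", ")),
          class = "boneagecal_row_error")
  }
  bad_sex <- which(is.na(cohort$sex))
  if (length(bad_sex) > 0) fail(bad_sex, "Missing or invalid sex")
  bad_ca <- which(is.na(cohort$ca) | cohort$ca <= 0)
  if (length(bad_ca) > 0) fail(bad_ca, "Chronological age must be a positive number")
  bad_gp <- which(!is.na(cohort$gp_ba) & cohort$gp_ba <= 0)
  if (length(bad_gp) > 0) fail(bad_gp, "GP bone age must be positive where present")
  bad_sms <- which(!is.na(cohort$sms) & (cohort$sms < 0 | cohort$sms > 1000))
  if (length(bad_sms) > 0) fail(bad_sms, "SMS must lie in [0, 1000]")
  invisible(cohort)
}

#' Read a cohort from a delimited text file
#'
#' The on-disk format is CSV with a mandatory header row; columns
#' `subject_id`, `sex`, `ca` are required and `city`, `gp_ba`, `sms`,
#' `tw3_manual`, `tw3_auto` are recognized when present. Empty fields
#' become `NA`. Row order is preserved.
#'
#' @param path file to read.
#' @param delim field delimiter, default comma.
#' @return a `ba_cohort` tibble (see [as_cohort()]).
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("Cohort file does not exist: %s", path),
          class = "boneagecal_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  as_cohort(raw, provenance = path)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: emits a header plus one row per record,
#' absent optional values as empty fields, numeric fields at full
#' precision so that a read/write round trip reproduces every field.
#'
#' @param cohort cohort data frame; must be nonempty.
#' @param path destination file.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  if (nrow(cohort) == 0) {
    abort("Refusing to write an empty cohort.", class = "boneagecal_domain_error")
  }
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "in-memory")
  out <- dplyr::mutate(
    tibble::as_tibble(cohort),
    dplyr::across(dplyr::where(is.numeric), ~ format_full(.x))
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# shortest decimal representation that still round-trips bit-exactly:
# try 15 significant digits, fall back to 17 where that loses bits
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == v) s else
      format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' @export
print.ba_cohort <- function(x, ...) {
  cat(sprintf("<ba_cohort> %d records (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown origin"))
  NextMethod()
}
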