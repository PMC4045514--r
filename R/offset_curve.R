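#' Piecewise-linear maturation offset curve
#'
#' An offset curve maps chronological age to a population maturation
#' offset (BA - CA) in years: piecewise-linear between knots, constant
#' beyond the first and last knot. It is the structure the synthetic
#' generator injects and the calibration step must recover -- e.g. a
#' population whose average bone age runs one year ahead of
#' chronological age by the end of puberty.
#'
#' @param ages strictly increasing knot ages in years (at least 2).
#' @param offsets offset in years at each knot.
#' @return a function of age, vectorized, of class `offset_curve`.
#' @examples
#' adv <- offset_curve(c(2, 10, 16, 20), c(0, 0, 1, 1))
#' adv(c(2, 13, 18))
#' @export
offset_curve <- function(ages, offsets) {
  stopifnot(length(ages) == length(offsets), length(ages) >= 2)
  if (any(diff(ages) <= 0)) {
    abort("Offset-curve knot ages must be strictly increasing.",
          class = "boneagecal_domain_error")
  }
  force(ages); force(offsets)
  f <- function(age) approx(ages, offsets, xout = age, rule = 2)$y
  structure(f, knots = tibble::tibble(age = ages, offset = offsets),
            class = c("offset_curve", "function"))
}

#' Constant offset curve
#'
#' Convenience wrapper: the same offset at every age.
#'
#' @param offset offset in years.
#' @return an [offset_curve()].
#' @export
constant_offset <- function(offset = 0) {
  offset_curve(c(2, 20), c(offset, offset))
}

#' @export
print.offset_curve <- function(x, ...) {
  cat("<offset_curve>\n")
  print(attr(x, "knots"))
  invisible(x)
}
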