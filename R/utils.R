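#' Round half away from zero
#'
#' Commercial ("half-up") rounding, matching the convention used when survey
#' reports print percentages: 0.05 rounds to 0.1, not to 0.0 as under the
#' IEEE banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.5)            # 3
#' round_half_up(74.78411, 1)    # 74.8
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards against 0.49999... artefacts of binary representation
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a denominator
#'
#' @param num Numerator count(s).
#' @param den Denominator count.
#' @param digits Decimal places (half-up); default 1, the reporting precision.
#' @return Percentage(s) on the 0-100 scale.
#' @examples
#' as_pct(433, 579)  # 74.8
#' @export
as_pct <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

# internal: stop with a consistent error class
wc_abort <- function(msg, class = "wellcount_error") {
  rlang::abort(msg, class = class)
}

# internal: check a vector is binary 0/1 (NA optionally allowed)
check_binary <- function(x, what = "indicator", allow_na = FALSE) {
  bad <- !(x %in% c(0, 1)) & !(allow_na & is.na(x))
  if (any(bad)) {
    wc_abort(sprintf("%s values must be 0 or 1 (found: %s)",
                     what, paste(utils::head(unique(x[bad]), 3), collapse = ", ")),
             class = "wellcount_type_error")
  }
  invisible(x)
}
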