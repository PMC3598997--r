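# shared helpers: percent parsing and the reporting rounding convention

#' Round half away from zero
#'
#' Rounding used when formatting impact fractions as printed percents
#' (`round()` in R rounds half to even, which disagrees with the convention
#' used in published scenario tables, e.g. 17.6703 -> 17.7).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.25, -0.5), 0)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Accepts 0.841, "0.841" or "84.1%"; returns a proportion in [0, 1].
parse_prevalence <- function(x) {
  if (is.numeric(x)) {
    return(x)
  }
  x <- trimws(as.character(x))
  pct <- grepl("%", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(gsub("%", "", x, fixed = TRUE)))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(paste0("cannot parse prevalence value(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  out[pct] <- out[pct] / 100
  out
}

# format a fraction as the percent string used in scenario tables
format_percent <- function(x, digits = 1) {
  paste0(format(round_half_away(100 * x, digits), nsmall = digits, trim = TRUE), "%")
}

stop_field <- function(risk_factor, sex, field, msg) {
  abort(sprintf("risk factor '%s' (%s), field '%s': %s", risk_factor, sex, field, msg))
}
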