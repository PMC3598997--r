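#' Generalized impact fraction over exposure distributions
#'
#' The generalized impact fraction (GIF) is the fractional reduction in
#' disease incidence obtained by shifting a risk factor's exposure
#' distribution from its observed ("fact") state \eqn{P} to a counterfactual
#' ("counter-fact") state \eqn{P'}:
#' \deqn{GIF = \frac{\sum_i P_i RR_i - \sum_i P'_i RR_i}{\sum_i P_i RR_i}}
#' where \eqn{RR_i} is the relative risk of exposure category \eqn{i} against
#' the reference category (\eqn{RR = 1}). The population attributable
#' fraction (PAF) is the special case in which the counterfactual places all
#' mass on the reference category.
#'
#' The value is at most 1 (complete elimination of the burden). It is
#' negative when the counterfactual distribution carries more RR-weighted
#' exposure than the fact distribution; such values are returned as-is, with
#' a warning, rather than clamped.
#'
#' @param fact numeric vector of fact proportions, one per exposure category,
#'   in `[0, 1]` and summing to 1 (tolerance 1e-9).
#' @param counterfact numeric vector of counterfactual proportions, same
#'   length and order as `fact`.
#' @param rr numeric vector of relative risks per category, all positive;
#'   the reference category has `rr = 1`.
#' @return `gif_value()` returns the fraction as a bare number.
#'   `gif()` returns a `gif_result` object (see [tidy.gif_result()]).
#' @seealso [paf()], [gif_binary()], [apply_scenario()]
#' @export
#' @examples
#' # shift low calcium/vitamin-D intake in women from 84.1% to 70% (RR 1.14)
#' gif_value(c(0.841, 0.159), c(0.70, 0.30), c(1.14, 1))
gif_value <- function(fact, counterfact, rr) {
  check_distribution(fact, "fact")
  check_distribution(counterfact, "counterfact")
  if (length(fact) != length(counterfact) || length(fact) != length(rr)) {
    abort("fact, counterfact and rr must have the same length")
  }
  if (any(!is.finite(rr)) || any(rr < 0)) {
    abort("relative risks must be finite and non-negative")
  }
  s_fact <- sum(fact * rr)
  if (s_fact <= 0) {
    abort("sum(fact * rr) must be positive; degenerate relative risks")
  }
  (s_fact - sum(counterfact * rr)) / s_fact
}

#' @param risk_factor,sex,scenario optional labels carried into the result.
#' @rdname gif_value
#' @export
gif <- function(fact, counterfact, rr,
                risk_factor = NA_character_, sex = NA_character_,
                scenario = NA_character_) {
  value <- gif_value(fact, counterfact, rr)
  if (value < 0) {
    warn(sprintf(
      "counterfactual increases RR-weighted exposure%s: GIF is negative (%.4g)",
      if (is.na(risk_factor)) "" else paste0(" for '", risk_factor, "'"), value))
  }
  structure(
    list(value = value, risk_factor = risk_factor, sex = sex,
         scenario = scenario, fact = fact, counterfact = counterfact,
         rr = rr, worsened = value < 0),
    class = "gif_result")
}

#' Population attributable fraction
#'
#' `paf()` evaluates [gif()] with the counterfactual distribution placing all
#' mass on the reference category (the category with relative risk 1), i.e.
#' complete elimination of exposure. For a binary risk factor this reduces to
#' the classical \eqn{P(RR-1) / (1 + P(RR-1))}.
#'
#' @inheritParams gif_value
#' @inheritParams gif
#' @return a `gif_result` object.
#' @export
#' @examples
#' paf(c(0.175, 0.825), c(1.59, 1))$value  # men's smoking: 0.0936
paf <- function(fact, rr, risk_factor = NA_character_, sex = NA_character_) {
  ref <- which(abs(rr - 1) < .Machine$double.eps^0.5)
  if (length(ref) == 0) {
    abort("no reference category: one category must have relative risk 1")
  }
  # ties at RR = 1 are harmless here: mass on any of them gives the same sum
  counterfact <- numeric(length(fact))
  counterfact[max(ref)] <- 1
  gif(fact, counterfact, rr, risk_factor = risk_factor, sex = sex,
      scenario = "full elimination")
}

#' Binary-exposure impact fraction
#'
#' Vectorized two-category GIF for exposed prevalence `p` shifted to
#' `p_prime` with relative risk `rr` (reference RR of 1 implied). This is the
#' form used by scenario tables where each risk factor is a yes/no exposure.
#'
#' @param p,p_prime fact and counterfactual exposed prevalences in `[0, 1]`.
#' @param rr relative risk of the exposed category.
#' @return numeric vector of impact fractions.
#' @export
#' @examples
#' gif_binary(0.421, 0.35, 1.56)  # 0.0322
gif_binary <- function(p, p_prime, rr) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(p_prime < 0 | p_prime > 1, na.rm = TRUE)) {
    abort("prevalences must lie in [0, 1]")
  }
  if (any(rr <= 0, na.rm = TRUE)) {
    abort("relative risk must be positive")
  }
  s_fact <- p * rr + (1 - p)
  (s_fact - (p_prime * rr + (1 - p_prime))) / s_fact
}

check_distribution <- function(x, what = "distribution") {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x))) {
    abort(sprintf("%s must be a numeric probability vector", what))
  }
  if (any(x < 0 | x > 1)) {
    abort(sprintf("%s proportions must lie in [0, 1]", what))
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(sprintf("%s proportions must sum to 1 (got %.12g)", what, sum(x)))
  }
  invisible(x)
}

#' @export
print.gif_result <- function(x, ...) {
  lbl <- if (is.na(x$risk_factor)) "" else paste0(" [", x$risk_factor,
    if (!is.na(x$sex)) paste0(", ", x$sex), "]")
  cat(sprintf("<gif_result>%s value = %.5f (%s)\n", lbl, x$value,
              format_percent(x$value)))
  invisible(x)
}

#' Tidy a GIF result
#'
#' @param x a `gif_result` from [gif()] or [paf()].
#' @param ... unused.
#' @return one-row tibble with the point estimate and its labels.
#' @export
tidy.gif_result <- function(x, ...) {
  tibble(risk_factor = x$risk_factor, sex = x$sex, scenario = x$scenario,
         gif_fraction = x$value,
         gif_percent = round_half_away(100 * x$value, 1),
         worsened = x$worsened)
}
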