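#' Validate a risk-factor configuration table
#'
#' A configuration is a long-format data frame with one row per exposure
#' category of each risk factor and sex:
#' `risk_factor`, `sex` ("female"/"male"), `age_group` (an opaque label such
#' as ">=50"; age groups are never harmonized across factors), `category`,
#' `relative_risk`, optional `rr_ci_low`/`rr_ci_high`, and `prevalence`.
#' Prevalences may be proportions (`0.841`), or percent strings (`"84.1%"`);
#' the two spellings load to identical values.
#'
#' When the reference category (relative risk 1) is omitted — the common case
#' for binary factors where only the exposed prevalence is published — it is
#' completed automatically with the complement prevalence. After completion
#' each factor must have at least two categories, prevalences summing to 1
#' within 1e-9, positive relative risks with exactly one reference, and any
#' confidence interval bracketing its point estimate.
#'
#' @param config data frame as described above.
#' @return a validated tibble (class `rf_config`) with reference rows
#'   completed, ordered by (risk_factor, sex) with the reference category last
#'   within each factor.
#' @export
#' @examples
#' cfg <- tibble::tibble(
#'   risk_factor = "smoking", sex = "female", age_group = ">=55",
#'   category = "exposed", relative_risk = 1.36,
#'   rr_ci_low = 1.12, rr_ci_high = 1.65, prevalence = "2.6%")
#' validate_config(cfg)
validate_config <- function(config) {
  if (!is.data.frame(config) || nrow(config) == 0) {
    abort("config must be a non-empty data frame: no risk factors found")
  }
  needed <- c("risk_factor", "sex", "relative_risk", "prevalence")
  missing <- setdiff(needed, names(config))
  if (length(missing)) {
    abort(paste0("config is missing column(s): ", paste(missing, collapse = ", ")))
  }
  config <- as_tibble(config)
  if (!"age_group" %in% names(config)) config$age_group <- NA_character_
  if (!"category" %in% names(config)) config$category <- "exposed"
  if (!"rr_ci_low" %in% names(config)) config$rr_ci_low <- NA_real_
  if (!"rr_ci_high" %in% names(config)) config$rr_ci_high <- NA_real_
  config$prevalence <- parse_prevalence(config$prevalence)
  if (!all(config$sex %in% c("female", "male"))) {
    abort("sex must be 'female' or 'male'")
  }

  out <- config |>
    dplyr::group_by(.data$risk_factor, .data$sex) |>
    dplyr::group_modify(~ complete_factor(.x, .y$risk_factor, .y$sex)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$risk_factor, .data$sex)
  new_tibble(out, class = "rf_config")
}

# per (risk_factor, sex): complete the reference category and check invariants
complete_factor <- function(rows, rf, sex) {
  chk <- function(field, ok, msg) if (!all(ok)) stop_field(rf, sex, field, msg)
  chk("prevalence", rows$prevalence >= 0 & rows$prevalence <= 1,
      sprintf("prevalence outside [0, 1] (%s)",
              paste(signif(rows$prevalence, 4), collapse = ", ")))
  chk("relative_risk", is.finite(rows$relative_risk) & rows$relative_risk > 0,
      "relative risk must be positive")
  has_ci <- !is.na(rows$rr_ci_low) | !is.na(rows$rr_ci_high)
  chk("rr_ci", !has_ci | (!is.na(rows$rr_ci_low) & !is.na(rows$rr_ci_high) &
        rows$rr_ci_low > 0 & rows$rr_ci_low <= rows$relative_risk &
        rows$relative_risk <= rows$rr_ci_high),
      "confidence interval must satisfy 0 < low <= RR <= high")

  is_ref <- abs(rows$relative_risk - 1) < 1e-12
  total <- sum(rows$prevalence)
  if (!any(is_ref)) {
    if (total > 1 + 1e-9) {
      stop_field(rf, sex, "prevalence",
                 sprintf("category prevalences sum to %.6g > 1; no room for a reference category", total))
    }
    rows <- dplyr::bind_rows(rows, tibble(
      age_group = rows$age_group[1], category = "reference",
      relative_risk = 1, rr_ci_low = NA_real_, rr_ci_high = NA_real_,
      prevalence = max(0, 1 - total)))
  } else {
    if (sum(is_ref) > 1) {
      stop_field(rf, sex, "relative_risk",
                 "more than one category has relative risk 1 (ambiguous reference)")
    }
    if (abs(total - 1) > 1e-9) {
      stop_field(rf, sex, "prevalence",
                 sprintf("full distribution supplied but prevalences sum to %.6g, not 1", total))
    }
    # keep the reference last so binary factors always read (exposed, reference)
    rows <- rows[order(is_ref), , drop = FALSE]
  }
  if (nrow(rows) < 2) stop_field(rf, sex, "categories", "at least 2 exposure categories required")
  if (anyDuplicated(rows$category)) stop_field(rf, sex, "category", "duplicate category labels")
  rows
}

#' Extract one risk factor's distributions from a configuration
#'
#' @param config validated configuration (or coercible via [validate_config()]).
#' @param risk_factor,sex which factor to extract.
#' @return list with `categories`, `rr`, `rr_ci_low`, `rr_ci_high`, `fact`
#'   (prevalence vector), `age_group`; reference category last.
#' @export
config_factor <- function(config, risk_factor, sex) {
  config <- ensure_config(config)
  rows <- dplyr::filter(config, .data$risk_factor == !!risk_factor, .data$sex == !!sex)
  if (nrow(rows) == 0) {
    abort(sprintf("risk factor '%s' (%s) not found in configuration", risk_factor, sex))
  }
  list(risk_factor = risk_factor, sex = sex, age_group = rows$age_group[1],
       categories = rows$category, rr = rows$relative_risk,
       rr_ci_low = rows$rr_ci_low, rr_ci_high = rows$rr_ci_high,
       fact = rows$prevalence)
}

ensure_config <- function(config) {
  if (inherits(config, "rf_config")) config else validate_config(config)
}

#' Direct standardization over demographic strata
#'
#' Weighted average of stratum-specific values (prevalences, rates) using a
#' fixed standard population's stratum weights, e.g. census age-group weights.
#' Weights are normalized to sum to 1 before use, so they may be supplied as
#' raw population counts.
#'
#' @param stratum_values data frame with columns `stratum` and `value`
#'   (values in `[0, 1]`).
#' @param standard data frame with columns `stratum` and `weight`
#'   (non-negative; any scale).
#' @return the standardized value, a single number between the minimum and
#'   maximum of the inputs.
#' @export
#' @examples
#' standardize(
#'   data.frame(stratum = c("50-64", "65+"), value = c(0.2, 0.5)),
#'   data.frame(stratum = c("50-64", "65+"), weight = c(0.7, 0.3)))  # 0.29
standardize <- function(stratum_values, standard) {
  for (nm in c("stratum", "value")) {
    if (!nm %in% names(stratum_values)) abort(paste0("stratum_values needs column '", nm, "'"))
  }
  for (nm in c("stratum", "weight")) {
    if (!nm %in% names(standard)) abort(paste0("standard needs column '", nm, "'"))
  }
  if (anyDuplicated(standard$stratum)) abort("duplicate stratum labels in standard population")
  if (anyDuplicated(stratum_values$stratum)) abort("duplicate stratum labels in stratum_values")
  if (any(standard$weight < 0) || sum(standard$weight) <= 0) {
    abort("standard weights must be non-negative with positive sum")
  }
  missing <- setdiff(standard$stratum, stratum_values$stratum)
  if (length(missing)) {
    abort(paste0("stratum_values is missing stratum(s): ", paste(missing, collapse = ", ")))
  }
  w <- standard$weight / sum(standard$weight)
  v <- stratum_values$value[match(standard$stratum, stratum_values$stratum)]
  if (any(v < 0 | v > 1)) abort("stratum values must lie in [0, 1]")
  sum(w * v)
}
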