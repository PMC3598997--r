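#' Apply a counterfactual scenario to a configuration
#'
#' A scenario names a counterfactual exposed prevalence per
#' (risk factor, sex), typically one of a graded family such as
#' "easy" / "moderate" / "difficult" (lowest through most ambitious reduction
#' in exposure prevalence). `apply_scenario()` handles binary risk factors
#' (the counterfactual distribution is `(target, 1 - target)`); use
#' [apply_scenario_general()] when a factor has more than two categories and
#' a full counterfactual distribution must be given.
#'
#' @param config risk-factor configuration (see [validate_config()]).
#' @param scenario data frame with columns `scenario`, `risk_factor`, `sex`,
#'   `counterfact_prevalence` (proportion or percent string) and optionally
#'   `flag` (free-text quality flags carried into the output, e.g. erratum
#'   markers from a source-data sidecar).
#' @return a burden-reduction table (tibble, class `burden_tbl`): one row per
#'   scenario target with `scenario`, `risk_factor`, `sex`, `age_group`,
#'   `fact_prev`, `cf_prev`, `gif_fraction` (full precision), `gif_percent`
#'   (one decimal, rounded half away from zero) and `flag`, sorted by
#'   (scenario, risk_factor, sex).
#' @seealso [gif_binary()], [combine_gif()], [autoplot.burden_tbl()]
#' @export
#' @examples
#' cfg <- hip_fracture_config()
#' sc <- tibble::tibble(scenario = "easy", risk_factor = "low_serum_vitd",
#'                      sex = "female", counterfact_prevalence = 0.35)
#' apply_scenario(cfg, sc)
apply_scenario <- function(config, scenario) {
  config <- ensure_config(config)
  scenario <- check_scenario_frame(scenario)
  if (nrow(scenario) == 0) {
    return(empty_burden_tbl())
  }
  rows <- purrr::pmap(scenario, function(scenario, risk_factor, sex,
                                         counterfact_prevalence, flag) {
    fac <- config_factor(config, risk_factor, sex)
    if (length(fac$rr) != 2) {
      abort(sprintf(
        "risk factor '%s' (%s) has %d categories; scenarios with a single target prevalence need a binary factor (use apply_scenario_general)",
        risk_factor, sex, length(fac$rr)))
    }
    value <- gif_value(fac$fact, c(counterfact_prevalence, 1 - counterfact_prevalence), fac$rr)
    tibble(scenario = scenario, risk_factor = risk_factor, sex = sex,
           age_group = fac$age_group, fact_prev = fac$fact[1],
           cf_prev = counterfact_prevalence, gif_fraction = value,
           gif_percent = round_half_away(100 * value, 1), flag = flag)
  })
  as_burden_tbl(dplyr::bind_rows(rows))
}

#' Apply a scenario given full counterfactual distributions
#'
#' Multi-category generalization of [apply_scenario()]: the scenario supplies
#' the complete counterfactual distribution, one row per exposure category.
#'
#' @inheritParams apply_scenario
#' @param scenario data frame with columns `scenario`, `risk_factor`, `sex`,
#'   `category`, `counterfact_prevalence`; categories must match the
#'   configuration (any omitted category gets the remaining mass only if it
#'   is the reference).
#' @return a `burden_tbl` as in [apply_scenario()]; `cf_prev` holds the
#'   counterfactual mass outside the reference category.
#' @export
apply_scenario_general <- function(config, scenario) {
  config <- ensure_config(config)
  if (nrow(scenario) == 0) {
    return(empty_burden_tbl())
  }
  for (nm in c("scenario", "risk_factor", "sex", "category", "counterfact_prevalence")) {
    if (!nm %in% names(scenario)) abort(paste0("scenario needs column '", nm, "'"))
  }
  scenario$counterfact_prevalence <- parse_prevalence(scenario$counterfact_prevalence)
  groups <- dplyr::group_split(dplyr::group_by(
    scenario, .data$scenario, .data$risk_factor, .data$sex))
  rows <- purrr::map(groups, function(g) {
    fac <- config_factor(config, g$risk_factor[1], g$sex[1])
    cf <- g$counterfact_prevalence[match(fac$categories, g$category)]
    if (anyNA(cf)) {
      miss <- fac$categories[is.na(cf)]
      ref_last <- fac$categories[length(fac$categories)]
      if (identical(miss, ref_last)) {
        cf[length(cf)] <- 1 - sum(cf, na.rm = TRUE)
      } else {
        abort(sprintf("counterfactual for '%s' (%s) missing category(ies): %s",
                      g$risk_factor[1], g$sex[1], paste(miss, collapse = ", ")))
      }
    }
    value <- gif_value(fac$fact, cf, fac$rr)
    n <- length(cf)
    tibble(scenario = g$scenario[1], risk_factor = g$risk_factor[1],
           sex = g$sex[1], age_group = fac$age_group,
           fact_prev = sum(fac$fact[-n]), cf_prev = sum(cf[-n]),
           gif_fraction = value,
           gif_percent = round_half_away(100 * value, 1), flag = NA_character_)
  })
  as_burden_tbl(dplyr::bind_rows(rows))
}

check_scenario_frame <- function(scenario) {
  for (nm in c("scenario", "risk_factor", "sex", "counterfact_prevalence")) {
    if (!nm %in% names(scenario)) abort(paste0("scenario needs column '", nm, "'"))
  }
  scenario <- as_tibble(scenario)
  if (!"flag" %in% names(scenario)) scenario$flag <- NA_character_
  scenario <- scenario[c("scenario", "risk_factor", "sex", "counterfact_prevalence", "flag")]
  scenario$counterfact_prevalence <- parse_prevalence(scenario$counterfact_prevalence)
  if (any(scenario$counterfact_prevalence < 0 | scenario$counterfact_prevalence > 1)) {
    abort("counterfact_prevalence must lie in [0, 1]")
  }
  dup <- duplicated(scenario[c("scenario", "risk_factor", "sex")])
  if (any(dup)) {
    abort(paste0("duplicate scenario target(s): ",
                 paste(unique(scenario$risk_factor[dup]), collapse = ", ")))
  }
  scenario
}

as_burden_tbl <- function(x) {
  x <- dplyr::arrange(x, .data$scenario, .data$risk_factor, .data$sex)
  new_tibble(as_tibble(x), class = "burden_tbl")
}

empty_burden_tbl <- function() {
  as_burden_tbl(tibble(
    scenario = character(), risk_factor = character(), sex = character(),
    age_group = character(), fact_prev = numeric(), cf_prev = numeric(),
    gif_fraction = numeric(), gif_percent = numeric(), flag = character()))
}
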