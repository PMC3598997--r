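#' Regenerate all scenario tables and combined estimates
#'
#' One call that runs the whole analysis: every scenario in `scenarios` is
#' applied to `config`, optional factor sets are combined under the
#' multiplicative and additive rules, and flags (erratum cells, capped sums,
#' mixed age groups) are collected. The run is fully deterministic — every
#' number in the report is recomputable from the recorded inputs.
#'
#' @param config risk-factor configuration.
#' @param scenarios scenario-target table (see [load_scenarios()]).
#' @param combine_sets optional named list describing factor sets to combine,
#'   each element a list with `risk_factors` (character vector) and `sex`;
#'   e.g. `list(diet = list(risk_factors = c("low_serum_vitd",
#'   "low_ca_vitd_intake"), sex = "female"))`.
#' @param methods combination rules to report (default both).
#' @return a `run_report`: list with `version`, `config_hash`,
#'   `scenario_hash`, `tables` (one `burden_tbl` over all scenarios),
#'   `combined` (tibble: set, scenario, sex, method, value, percent, capped),
#'   and `warnings` (character).
#' @export
run_tables <- function(config, scenarios, combine_sets = NULL,
                       methods = c("multiplicative", "additive")) {
  config <- ensure_config(config)
  scenarios <- check_scenario_frame(scenarios)
  msgs <- character()
  catch <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  tables <- catch(apply_scenario(config, scenarios))
  flagged <- dplyr::filter(tables, !is.na(.data$flag) & .data$flag != "")
  if (nrow(flagged)) {
    msgs <- c(msgs, sprintf("flagged cell: %s/%s/%s [%s]", flagged$scenario,
                            flagged$risk_factor, flagged$sex, flagged$flag))
  }
  combined <- empty_combined_tbl()
  for (set_name in names(combine_sets)) {
    set <- combine_sets[[set_name]]
    for (sc in unique(tables$scenario)) {
      rows <- dplyr::filter(tables, .data$scenario == sc,
                            .data$risk_factor %in% set$risk_factors,
                            .data$sex == set$sex)
      if (nrow(rows) != length(set$risk_factors)) {
        abort(sprintf("combine set '%s': not all factors present in scenario '%s'",
                      set_name, sc))
      }
      set_sex <- set$sex
      for (m in methods) {
        cg <- catch(combine_gif(rows, m))
        combined <- dplyr::bind_rows(combined, tibble(
          set = set_name, scenario = sc, sex = set_sex, method = m,
          value = cg$value, percent = round_half_away(100 * cg$value, 1),
          capped = cg$capped))
      }
    }
  }
  structure(list(
    version = as.character(utils::packageVersion("impactfrac")),
    config_hash = rlang::hash(as_tibble(config)),
    scenario_hash = rlang::hash(as_tibble(scenarios)),
    tables = tables, combined = combined, warnings = unique(msgs)),
    class = "run_report")
}

empty_combined_tbl <- function() {
  tibble(set = character(), scenario = character(), sex = character(),
         method = character(), value = numeric(), percent = numeric(),
         capped = logical())
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> impactfrac %s | %d table row(s), %d combined estimate(s), %d warning(s)\n",
              x$version, nrow(x$tables), nrow(x$combined), length(x$warnings)))
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_tables()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- list(version = report$version, config_hash = report$config_hash,
              scenario_hash = report$scenario_hash,
              tables = as_tibble(report$tables), combined = report$combined,
              warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Counterfactual prevalence achieving a target impact fraction
#'
#' Closed-form inverse of the binary GIF: for a factor with exposed
#' prevalence `p` and relative risk `rr`, the counterfactual prevalence
#' giving impact fraction `g` is
#' \eqn{p' = p - g (1 + p(rr - 1)) / (rr - 1)}.
#' Feasible targets run from 0 (no change) to the attributable fraction
#' (full elimination); anything larger is rejected.
#'
#' @param p fact exposed prevalence in `[0, 1]`.
#' @param rr relative risk of the exposed category (> 0, not 1).
#' @param desired_gif target impact fraction.
#' @return the counterfactual exposed prevalence.
#' @export
#' @examples
#' inverse_target(0.421, 1.56, 0.0322)  # ~0.35
inverse_target <- function(p, rr, desired_gif) {
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  if (rr <= 0 || rr == 1) abort("rr must be positive and different from 1")
  max_gif <- gif_binary(p, 0, rr)
  if (desired_gif > max_gif + 1e-12) {
    abort(sprintf("desired GIF %.4g exceeds the attributable fraction %.4g (infeasible even at full elimination)",
                  desired_gif, max_gif))
  }
  p_prime <- p - desired_gif * (1 + p * (rr - 1)) / (rr - 1)
  min(max(p_prime, 0), 1)
}
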