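#' Load a risk-factor configuration from CSV
#'
#' Expects the long format documented in [validate_config()]; prevalence
#' cells may be proportions or percent strings. The returned configuration
#' is validated, with reference categories completed.
#'
#' @param path CSV file.
#' @return an `rf_config` tibble.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(prevalence = readr::col_character()))
  if (nrow(raw) == 0) abort(paste0("no risk factors in ", path))
  validate_config(raw)
}

#' Load a scenario table from CSV
#'
#' Columns `scenario`, `risk_factor`, `sex`, `counterfact_prevalence`
#' (proportion or percent string) and optionally `flag`.
#'
#' @param path CSV file.
#' @return tibble of scenario targets.
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           counterfact_prevalence = readr::col_character()))
  check_scenario_frame(raw)
}

#' Serialize a configuration back to CSV
#'
#' Inverse of [load_config()] up to the percent/proportion spelling:
#' `load_config(write_config(cfg, f))` is value-identical to `cfg`.
#'
#' @param config an `rf_config`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- ensure_config(config)
  readr::write_csv(as_tibble(config), path)
  invisible(path)
}

#' Write a burden table as TSV
#'
#' Mirrors the published scenario-table layout: identifying columns, fact
#' and counterfactual prevalence and the burden reduction as a one-decimal
#' percent, with the raw fraction alongside at full precision.
#'
#' @param tbl a `burden_tbl` from [apply_scenario()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(tbl, path) {
  out <- dplyr::mutate(as_tibble(tbl),
                       fact_prev = format_percent(.data$fact_prev, 1),
                       cf_prev = format_percent(.data$cf_prev, 1))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Bundled osteoporotic hip-fracture inputs
#'
#' The package ships the published inputs for five modifiable risk factors of
#' osteoporotic hip fracture in the Iranian population aged 50+ (by sex):
#' low calcium/vitamin-D intake, low serum vitamin D, current smoking, low
#' physical activity and low BMI, each with exposed prevalence, relative
#' risk and 95% CI, plus the easy/moderate/difficult counterfactual
#' prevalence targets and the published one-decimal burden-reduction
#' percents. `hip_fracture_errata()` lists the source cells whose printed
#' values recomputation contradicts (see the package vignette); cells it
#' names are flagged in the other tables rather than silently corrected.
#'
#' @return `hip_fracture_config()`: an `rf_config` (10 factor-sex records).
#'   `hip_fracture_scenarios()`: 30 scenario targets.
#'   `hip_fracture_printed_burden()`: published burden percents with erratum
#'   flags and recomputed values for flagged cells.
#'   `hip_fracture_errata()`: the erratum sidecar.
#' @export
#' @examples
#' apply_scenario(hip_fracture_config(),
#'                dplyr::filter(hip_fracture_scenarios(), scenario == "easy"))
hip_fracture_config <- function() {
  load_config(extdata("hip_fracture_risk_factors.csv"))
}

#' @rdname hip_fracture_config
#' @export
hip_fracture_scenarios <- function() {
  load_scenarios(extdata("hip_fracture_scenarios.csv"))
}

#' @rdname hip_fracture_config
#' @export
hip_fracture_printed_burden <- function() {
  readr::read_csv(extdata("hip_fracture_printed_burden.csv"),
                  show_col_types = FALSE)
}

#' @rdname hip_fracture_config
#' @export
hip_fracture_errata <- function() {
  readr::read_csv(extdata("hip_fracture_errata.csv"), show_col_types = FALSE)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "impactfrac")
  if (path == "") {
    abort(paste0("bundled file not found: ", file))
  }
  path
}
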