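#' Simulate individual-level cohorts under fact and counterfactual exposure
#'
#' Brute-force counterpart of the analytic GIF: two cohorts of `n`
#' individuals are assigned exposure categories multinomially (fact world
#' from `fact`, counterfactual world from `counterfact`) and a one-period
#' fracture event is drawn per individual with probability
#' `baseline_risk * rr[category]`. The GIF estimated from the two event
#' rates ([empirical_gif()]) converges to the analytic value, which is what
#' makes this a validation oracle for the formula. The risk model is a
#' single-period Bernoulli probability, not a hazard over time: the GIF is a
#' one-shot fraction, so no time-to-event machinery is used, and the RR is
#' applied as a risk ratio (adequate at the low baseline risks of interest;
#' `baseline_risk` defaults to 0.01 accordingly).
#'
#' With `common_random = TRUE` the two worlds share the latent uniforms for
#' both exposure assignment and events, which removes most Monte-Carlo noise
#' from the *difference* between worlds (variance reduction for oracle
#' tests); by default the worlds are independent.
#'
#' @param n number of individuals per world.
#' @param baseline_risk event probability in the reference category, in
#'   (0, 1); `baseline_risk * max(rr)` must not exceed 1.
#' @param fact,counterfact exposure distributions (full probability vectors,
#'   or single exposed prevalences for a binary factor).
#' @param rr relative risks per category (scalar for a binary factor).
#' @param seed integer seed; draws are scoped to the call.
#' @param common_random share latent uniforms between worlds.
#' @return a `sim_cohort` tibble with one row per individual and columns
#'   `world` ("fact"/"counterfact"), `category` (integer index; the reference
#'   is the last category) and `event` (0/1). The RR vector and reference
#'   index are carried in attributes `rr` and `reference`.
#' @seealso [empirical_gif()], [recover_rr()]
#' @export
#' @examples
#' ch <- simulate_cohort(20000, 0.05, fact = 0.671, counterfact = 0.30,
#'                       rr = 1.7, seed = 1)
#' empirical_gif(ch)
simulate_cohort <- function(n, baseline_risk, fact, counterfact, rr,
                            seed = NULL, common_random = FALSE) {
  stopifnot(n >= 1)
  if (baseline_risk <= 0 || baseline_risk >= 1) {
    abort("baseline_risk must lie in (0, 1)")
  }
  dists <- as_binary_pair(fact, counterfact, rr)
  fact <- dists$fact; counterfact <- dists$counterfact; rr <- dists$rr
  check_distribution(fact, "fact")
  check_distribution(counterfact, "counterfact")
  if (baseline_risk * max(rr) > 1) {
    abort(sprintf("baseline_risk * max(rr) = %.3f exceeds 1: not a probability",
                  baseline_risk * max(rr)))
  }
  k <- length(rr)
  out <- with_seed_maybe(seed, {
    if (common_random) {
      u_cat <- runif(n)
      u_ev <- runif(n)
      cat_f <- draw_categories(u_cat, fact)
      cat_c <- draw_categories(u_cat, counterfact)
      ev_f <- as.integer(u_ev < baseline_risk * rr[cat_f])
      ev_c <- as.integer(u_ev < baseline_risk * rr[cat_c])
    } else {
      cat_f <- draw_categories(runif(n), fact)
      ev_f <- rbinom(n, 1L, baseline_risk * rr[cat_f])
      cat_c <- draw_categories(runif(n), counterfact)
      ev_c <- rbinom(n, 1L, baseline_risk * rr[cat_c])
    }
    tibble(world = rep(c("fact", "counterfact"), each = n),
           category = c(cat_f, cat_c), event = c(ev_f, ev_c))
  })
  structure(new_tibble(out, class = "sim_cohort"),
            rr = rr, reference = k, baseline_risk = baseline_risk)
}

# inverse-CDF multinomial assignment from shared uniforms
draw_categories <- function(u, p) {
  findInterval(u, cumsum(p)[-length(p)], left.open = FALSE) + 1L
}

#' Empirical impact fraction from a simulated two-world cohort
#'
#' `(rate_fact - rate_counterfact) / rate_fact` from the per-world event
#' rates. `empirical_gif_se()` gives its delta-method standard error from the
#' binomial counts, used for "within 3 SE of the analytic value" checks.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()], or any data frame
#'   with `world` and `event` columns covering both worlds.
#' @return a single number.
#' @export
empirical_gif <- function(cohort) {
  r <- world_rates(cohort)
  if (r$events[r$world == "fact"] == 0) {
    abort("no events in the fact world: empirical GIF undefined")
  }
  rate <- r$events / r$n
  (rate[r$world == "fact"] - rate[r$world == "counterfact"]) / rate[r$world == "fact"]
}

#' @rdname empirical_gif
#' @export
empirical_gif_se <- function(cohort) {
  r <- world_rates(cohort)
  pf <- r$events[r$world == "fact"] / r$n[r$world == "fact"]
  pc <- r$events[r$world == "counterfact"] / r$n[r$world == "counterfact"]
  ratio <- pc / pf
  # var of a ratio of independent binomial proportions, delta method
  ratio * sqrt((1 - pf) / (pf * r$n[r$world == "fact"]) +
               (1 - pc) / (pc * r$n[r$world == "counterfact"]))
}

world_rates <- function(cohort) {
  if (!all(c("world", "event") %in% names(cohort))) {
    abort("cohort needs 'world' and 'event' columns")
  }
  r <- dplyr::summarise(dplyr::group_by(as_tibble(cohort), .data$world),
                        events = sum(.data$event), n = dplyr::n(),
                        .groups = "drop")
  if (!all(c("fact", "counterfact") %in% r$world)) {
    abort("cohort must contain both a 'fact' and a 'counterfact' world")
  }
  if (any(r$n == 0)) abort("empty cohort")
  r
}

#' Recover per-category relative risks from a simulated cohort
#'
#' Ratio of the observed event rate in each category to the reference
#' category's rate, from the fact world. Used to close the loop in parameter
#' recovery: simulate with known RRs, re-estimate them, and feed the
#' estimates back through [gif_value()].
#'
#' @param cohort a `sim_cohort`.
#' @param world which world to estimate from (default "fact").
#' @return tibble with `category`, `n`, `events`, `rate`, `rr_hat`,
#'   `se_log_rr` (NA for the reference).
#' @export
recover_rr <- function(cohort, world = "fact") {
  ref <- attr(cohort, "reference")
  rr <- attr(cohort, "rr")
  if (is.null(ref)) abort("cohort lacks a 'reference' attribute; was it built by simulate_cohort()?")
  d <- dplyr::filter(as_tibble(cohort), .data$world == !!world)
  tab <- dplyr::summarise(dplyr::group_by(d, .data$category),
                          n = dplyr::n(), events = sum(.data$event),
                          .groups = "drop")
  missing <- setdiff(seq_along(rr), tab$category)
  if (length(missing)) {
    abort(paste0("no individuals observed in category(ies): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- dplyr::arrange(tab, .data$category)
  if (tab$events[ref] == 0) abort("zero events in the reference category")
  tab$rate <- tab$events / tab$n
  tab$rr_hat <- tab$rate / tab$rate[ref]
  tab$se_log_rr <- sqrt(1 / tab$events - 1 / tab$n +
                        1 / tab$events[ref] - 1 / tab$n[ref])
  tab$se_log_rr[ref] <- NA_real_
  tab
}
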