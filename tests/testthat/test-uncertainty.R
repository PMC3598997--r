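test_that("the lognormal RR model matches its published interval", {
  par <- rr_lognormal_params(1.56, 1.12, 2.17)
  expect_equal(par$sdlog, 0.1687272, tolerance = 1e-6)
  expect_equal(par$meanlog, log(1.56))
  # the point estimate sits at the geometric mean of its interval
  expect_equal(sqrt(1.12 * 2.17), 1.56, tolerance = 1e-3)

  draws <- sample_rr(1.56, 1.12, 2.17, n_draws = 10000, seed = 4)
  expect_true(all(draws > 0))
  # law of large numbers: mean log draw within 3 sigma / sqrt(n) of log RR
  expect_lt(abs(mean(log(draws)) - log(1.56)),
            3 * par$sdlog / sqrt(10000))
  # degenerate interval: all draws collapse to the point estimate
  expect_identical(sample_rr(1.56, 1.56, 1.56, 50, seed = 1), rep(1.56, 50))
  expect_error(sample_rr(1.56, NA, NA, 10), "confidence interval required")
})

test_that("gif_interval is deterministic under a fixed seed", {
  a <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 4000, seed = 42)
  b <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 4000, seed = 42)
  expect_identical(c(a$low, a$high), c(b$low, b$high))
  expect_lte(a$low, a$high)
  # a different seed agrees within Monte-Carlo error at this width
  c2 <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 10000, seed = 43)
  a2 <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 10000, seed = 42)
  expect_lt(abs((a2$high - a2$low) - (c2$high - c2$low)),
            0.10 * (a2$high - a2$low))
})

test_that("interval endpoints match the analytic monotone-map oracle", {
  # for a binary factor with P > P', GIF is increasing in RR, so the interval
  # endpoints are the GIF at the RR draw quantiles
  seed <- 12; n <- 8000
  iv <- gif_interval(0.421, 0.25, 1.56, 1.12, 2.17, n_draws = n, seed = seed)
  rr_draws <- sample_rr(1.56, 1.12, 2.17, n, seed = seed)
  qs <- quantile(rr_draws, c(0.025, 0.975), names = FALSE)
  # agreement up to the quantile interpolation between order statistics
  # (the map is nonlinear, so interpolating before vs after transforming
  # differs at ~1e-9 for these widths)
  expect_equal(iv$low, gif_binary(0.421, 0.25, qs[1]), tolerance = 1e-6)
  expect_equal(iv$high, gif_binary(0.421, 0.25, qs[2]), tolerance = 1e-6)
  # the point estimate uses the published RR, inside a strictly positive band
  expect_equal(iv$point, gif_binary(0.421, 0.25, 1.56))
  expect_gt(iv$low, 0)  # ci_low > 1 keeps the whole band positive
})

test_that("no uncertainty collapses the interval; wider CIs widen it", {
  f <- gif_interval(0.421, 0.35, 1.56, rr_model = "fixed", seed = 1)
  expect_identical(c(f$low, f$point, f$high), rep(f$point, 3))
  narrow <- gif_interval(0.421, 0.35, 1.56, 1.3, 1.9, n_draws = 5000, seed = 42)
  wide <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 5000, seed = 42)
  expect_lt(narrow$high - narrow$low, wide$high - wide$low)
})

test_that("prevalence uncertainty is available through the beta model", {
  fixed <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 5000, seed = 2)
  beta <- gif_interval(0.421, 0.35, 1.56, 1.12, 2.17, n_draws = 5000, seed = 2,
                       prev_model = "beta", effective_n = 300)
  expect_gt(beta$high - beta$low, fixed$high - fixed$low)
  expect_error(gif_interval(0.421, 0.35, 1.56, 1.12, 2.17,
                            prev_model = "beta"), "effective_n")
})

test_that("combined intervals are deterministic and sharing draws narrows nothing by accident", {
  cfg <- hip_fracture_config()
  tg <- tibble::tibble(risk_factor = c("low_serum_vitd", "low_ca_vitd_intake"),
                       sex = "female", counterfact_prevalence = c(0.15, 0.40))
  a <- combined_gif_interval(cfg, tg, n_draws = 4000, seed = 5)
  b <- combined_gif_interval(cfg, tg, n_draws = 4000, seed = 5)
  expect_identical(tidy(a), tidy(b))
  expect_equal(a$point, 0.1712601, tolerance = 1e-6)
  expect_true(a$low < a$point && a$point < a$high)
  shared <- combined_gif_interval(cfg, tg, n_draws = 4000, seed = 5,
                                  share_rr = TRUE)
  expect_true(shared$low <= shared$high)
})
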