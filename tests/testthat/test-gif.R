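test_that("gif_value reproduces hand-computed shifts", {
  # women's low calcium/vitamin-D intake, 84.1% -> 70% at RR 1.14
  expect_equal(gif_value(c(0.841, 0.159), c(0.70, 0.30), c(1.14, 1)),
               0.01766064, tolerance = 1e-6)
  # three-category shift, evaluated by hand: (1.65 - 1.35) / 1.65
  expect_equal(gif_value(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5), c(2, 1.5, 1)),
               0.3 / 1.65)
  # null shift is exactly zero whatever the risks
  for (rr in list(c(3, 1), c(1.2, 0.8, 1))) {
    p <- random_distribution(length(rr))
    expect_identical(gif_value(p, p, rr), 0)
  }
})

test_that("gif_value rejects invalid inputs", {
  expect_error(gif_value(c(0.5, 0.4), c(0.5, 0.5), c(2, 1)), "sum to 1")
  expect_error(gif_value(c(0.5, 0.5), c(0.5, 0.5), c(2, 1, 1)), "same length")
  expect_error(gif_value(c(0.5, 0.5), c(1.2, -0.2), c(2, 1)), "\\[0, 1\\]")
  expect_error(gif_value(c(0, 1), c(1, 0), c(1, 0)), "positive")
})

test_that("paf equals the closed form and the full-elimination gif", {
  # men's smoking: P = 0.175, RR = 1.59 -> 0.175*0.59/1.10325
  expect_equal(paf(c(0.175, 0.825), c(1.59, 1))$value, 0.09358713,
               tolerance = 1e-6)
  expect_identical(paf(c(0, 1), c(1.59, 1))$value, 0)       # nobody exposed
  expect_equal(paf(c(0.3, 0.4, 0.3), c(1, 1, 1))$value, 0)  # harmless exposure

  withr::with_seed(11, {
    for (i in 1:25) {
      k <- sample(2:5, 1)
      p <- random_distribution(k)
      rr <- c(runif(k - 1, 0.5, 4), 1)
      ref_mass <- numeric(k); ref_mass[k] <- 1
      # some draws have rr < 1, where elimination worsens things and warns
      v <- suppressWarnings(paf(p, rr)$value)
      expect_equal(v, gif_value(p, ref_mass, rr))
      if (k == 2) {
        expect_equal(v, binary_closed_form(p[1], 0, rr[1]))
      }
    }
  })
})

test_that("gif agrees with an independent expected-incidence oracle", {
  withr::with_seed(7, {
    for (i in 1:40) {
      k <- sample(2:5, 1)
      p <- random_distribution(k)
      q <- random_distribution(k)
      rr <- c(runif(k - 1, 0.3, 5), 1)
      expect_equal(gif_value(p, q, rr),
                   expected_incidence_gif(p, q, rr, baseline = runif(1, 0.001, 0.1)))
    }
  })
})

test_that("binary gif matches the closed form and is monotone in the target", {
  withr::with_seed(5, {
    for (i in 1:40) {
      p <- runif(1); pp <- runif(1); rr <- runif(1, 0.2, 6)
      expect_equal(gif_binary(p, pp, rr), binary_closed_form(p, pp, rr))
    }
  })
  # gif strictly decreases as the counterfactual exposed prevalence grows
  targets <- seq(0, 0.6, by = 0.05)
  g <- gif_binary(0.671, targets, 1.7)
  expect_true(all(diff(g) < 0))
})

test_that("gif result objects carry labels, warn on worsening, and tidy", {
  r <- gif(c(0.3, 0.7), c(0.1, 0.9), c(2, 1), risk_factor = "x", sex = "female")
  expect_s3_class(r, "gif_result")
  expect_false(r$worsened)
  expect_warning(gif(c(0.1, 0.9), c(0.5, 0.5), c(2, 1)), "negative")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$risk_factor, "x")
  expect_equal(td$gif_fraction, r$value)
  expect_true(r$value <= 1)
})
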