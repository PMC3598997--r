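# Independent oracles used across tests. These re-derive the impact fraction
# from first principles (expected incidence under each world) rather than
# calling the package's formula, so agreement is a real check.

# expected event rate at baseline b under exposure distribution p:
# E[rate] = b * sum(p * rr); the impact fraction is the fractional drop.
expected_incidence_gif <- function(fact, counterfact, rr, baseline = 0.013) {
  rate_fact <- baseline * sum(fact * rr)
  rate_cf <- baseline * sum(counterfact * rr)
  (rate_fact - rate_cf) / rate_fact
}

# closed form for a binary factor: (P - P')(RR - 1) / (1 + P(RR - 1))
binary_closed_form <- function(p, p_prime, rr) {
  (p - p_prime) * (rr - 1) / (1 + p * (rr - 1))
}

# random valid exposure distribution over k categories
random_distribution <- function(k) {
  x <- runif(k)
  x / sum(x)
}

women_vitd <- list(p = 0.421, rr = 1.56, ci = c(1.12, 2.17))
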