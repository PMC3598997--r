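---
title: "Generalized impact fractions: model, data handling and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized impact fractions: model, data handling and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactfrac)
library(dplyr)
```

## The model

For a risk factor partitioned into exposure categories with fact
distribution $P = (P_1, \dots, P_n)$, counterfactual distribution
$P' = (P'_1, \dots, P'_n)$ and relative risks $RR_i$ (reference category
$RR = 1$), the generalized impact fraction is

$$\mathrm{GIF} = \frac{\sum_i P_i RR_i - \sum_i P'_i RR_i}{\sum_i P_i RR_i}.$$

The denominator $\sum_i P_i RR_i$ is the expected incidence under the fact
world relative to a fully unexposed population, so the GIF is exactly the
fractional drop in expected incidence caused by the prevalence shift. Three
consequences the package relies on:

- **GIF $\le$ 1 always**, with equality only at complete elimination of all
  excess risk. A counterfactual that *worsens* exposure yields a negative
  GIF; we return it (with a warning) rather than clamping, because the index
  is well defined for any shift.
- **PAF is the special case** $P'$ = all mass on the reference:
  $P(RR-1)/(1+P(RR-1))$ for a binary factor. `paf()` is implemented through
  `gif()` this way, and the closed form is a test identity, not the
  implementation.
- The GIF uses **crude (unadjusted) relative risks**. An adjusted effect
  measure cannot be pushed through the formula; if confounding matters one
  must stratify and apply the formula per stratum with crude stratum RRs.
  The package deliberately offers no confounder adjustment.

Binary factors are handled as the two-category special case of the general
machinery — one code path, with the reference category always stored last.

## The bundled hip-fracture configuration

The package ships the published inputs for five modifiable risk factors of
osteoporotic hip fracture (by sex, Iranian population): low calcium and
vitamin-D intake (ages 50+, RR 1.14), low serum vitamin D (65+, RR 1.56),
current smoking (55+, RR 1.36 women / 1.59 men), low physical activity (50+,
RR 1.70) and low BMI (50+, RR 1.79), with 95% CIs and exposed prevalences.
Age groups are opaque labels: the source literature defines different
factors on different age ranges and we make no attempt to harmonize them
(combination across mixed age groups warns and proceeds).

Prevalences are stored as proportions in $[0,1]$ throughout; percent is a
presentation concern only, which avoids double-conversion bugs against
tables that print percents.

```{r}
hip_fracture_config()
```

### Errata in the source tables

Regenerating the published easy/moderate/difficult burden-reduction tables
from these inputs reproduces 26 of the 30 printed one-decimal percents
exactly, plus one cell that matches only after repairing its input. The
remaining discrepancies are recorded in a sidecar rather than silently
corrected, and the affected cells are flagged in every output:

```{r}
hip_fracture_errata()
```

- The women's serum-vitamin-D prevalence is printed as 41.2% in the input
  frequency table but used as 42.1% everywhere else; 42.1% reproduces every
  burden cell (41.2% reproduces none), so it is canonical here.
- Three moderate-scenario cells recompute one printed decimal lower than
  published (3.6 vs 3.7, 0.7 vs 0.8, 7.7 vs 7.8). The last is consistent
  with rounding in two steps (7.7491 → 7.75 → 7.8); we round once, half away
  from zero, and assert the recomputed values in tests.
- The men's smoking moderate prediction (printed 1%) is inconsistent with
  both the ordering of the scenarios and its own printed burden of 2.5%; the
  prediction implied by 2.5% (≈12.8%) is stored, flagged
  `imputed_prediction`.

## Scenarios and combination

A scenario is just a named set of counterfactual prevalence targets — the
labels easy/moderate/difficult carry no semantics beyond their values.
`apply_scenario()` recomputes every cell through the engine, so each table
row round-trips bit-identically.

Two combination rules are exposed because the right one is genuinely
ambiguous. The multiplicative rule $1 - \prod_k (1 - g_k)$ assumes each
intervention removes its fraction of the burden *left by the others*; the
additive rule $\min(1, \sum_k g_k)$ assumes disjoint burden pools and is
capped. For nonnegative components multiplicative $\le$ additive, with
equality iff at most one component is nonzero. For the bundled data the
two-factor dietary figures (≈5/11/17% across scenarios) agree with the
multiplicative rule at nearest-percent rounding, and the three-factor easy
figure (≈8%) with either rule; the three-factor moderate and difficult
combinations differ materially between rules (20.5% vs 21.9%; 31.8% vs
35.5%), so `run_tables()` always reports both and asserts neither.

## Uncertainty

Published RRs carry 95% CIs; the default propagation model treats
$\log RR$ as normal with $\mu = \log RR$ and
$\sigma = (\log hi - \log lo)/(2 \cdot z_{0.975})$. This is self-consistent
when the point estimate sits at the geometric mean of its interval, which
holds within 0.1% for all five bundled factors. Intervals are equal-tailed
empirical quantiles of the GIF over draws (default 10,000), deterministic
given a seed: draws are consumed category by category, then draw by draw.
For a binary factor with reduced exposure the GIF is monotone in RR, so the
interval endpoints coincide with the GIF at the RR quantiles — used as an
analytic cross-check in the tests, to quantile-interpolation accuracy.

Prevalence uncertainty defaults to *fixed* because the sources publish no
prevalence standard errors; an opt-in Dirichlet/beta model with a
user-chosen effective sample size is available. RRs of different risk
factors are sampled independently by default; `share_rr = TRUE` reuses one
stream for factors whose published RR and CI are numerically identical
(several factor pairs share a single sex-pooled estimate). The source
analysis reports no uncertainty on its impact fractions, so intervals are an
extension of this package and are never mixed into the table reproduction.

```{r}
gif_interval(0.421, 0.35, rr = 1.56, rr_ci_low = 1.12, rr_ci_high = 2.17,
             n_draws = 5000, seed = 42)
```

## The cohort simulator

`simulate_cohort()` is both the synthetic-data generator and the brute-force
oracle. Each of two worlds assigns `n` individuals to exposure categories
multinomially (fact vs counterfactual distribution) and draws a one-period
fracture event with probability `baseline_risk * rr[category]`. Design
choices:

- **Single-period Bernoulli risk, no hazards.** The GIF is a one-shot
  fraction of incidence, so time-to-event machinery would add nothing the
  statistic can see.
- **RR applied as a risk ratio.** Source effect measures mix risk, odds and
  hazard ratios; at hip-fracture incidences the rare-disease approximation
  makes these interchangeable, and the default `baseline_risk` of 0.01
  keeps the simulation in that regime. The empirical GIF is invariant to the
  baseline in expectation (it is a fraction, not a rate), which is itself
  tested at two baselines.
- **Independent worlds by default**, with a common-random-numbers mode
  (shared latent uniforms for both category assignment and events) that
  removes most Monte-Carlo noise from the between-world contrast when a
  tight oracle comparison is wanted.

The validation loop: empirical GIF $(r_f - r_{cf})/r_f$ agrees with the
analytic value within 3 delta-method standard errors for every factor-sex
combination at $n = 10^6$; `recover_rr()` re-estimates each category's RR as
a rate ratio, and the GIF recomputed from the recovered parameters brackets
the analytic value within propagated (3 SE corner) error. What this does
*not* show: the simulator draws exactly the model the formula assumes
(marginal exposure, multiplicative risk, no confounding, no correlation
between risk factors), so passing oracle tests validates the *arithmetic*,
not the epidemiological assumptions against real cohorts.

```{r}
ch <- simulate_cohort(2e5, 0.01, fact = 0.671, counterfact = 0.30,
                      rr = 1.7, seed = 1)
c(empirical = empirical_gif(ch), analytic = gif_binary(0.671, 0.30, 1.7))
```

## Numerical conventions and degenerate inputs

- Distributions must sum to 1 within `1e-9`; reference-category completion
  makes this exact up to one floating-point subtraction.
- Printed percents round **half away from zero** at one decimal (two
  decimals where a finer figure is quoted), matching the apparent convention
  of the source tables; raw fractions are always emitted alongside, and the
  engine itself never rounds.
- $\sum_i P_i RR_i = 0$ (all-zero RR weight) is rejected rather than
  returning NaN.
- `inverse_target()` solves the binary GIF for the counterfactual
  prevalence, $p' = p - g(1 + p(rr-1))/(rr-1)$, rejecting targets above the
  attributable fraction; `gif(inverse(g)) = g` to `1e-12` is a property
  test.
- Ties at RR = 1 when locating the reference for `paf()` are broken by
  taking the last such category — any choice gives the same value since the
  tied categories contribute identically.
- Direct standardization normalizes weights first, so census counts and
  proportions are equally valid input.

## Problem sizes

Test and validation runs use $n = 10^6$ individuals per world for the
oracle-equivalence and parameter-recovery checks (binomial SEs of the
empirical GIF around 0.005 at the default baseline), 500 replicates at
2,000 draws each for interval coverage (Monte-Carlo SE of the coverage
estimate ≈1%), and 10,000 draws for production intervals. These sizes put
the Monte-Carlo error comfortably below the 3-SE acceptance bands while
keeping the full suite fast.

## Limitations

Everything is marginal: no joint-exposure modelling, no interaction between
risk factors, no confounder adjustment, no competing risks or
post-fracture mortality. Scenario targets are taken as given — the package
inverts a target burden into a prevalence (`inverse_target()`) but does not
judge feasibility of interventions.
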