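---
title: "Estimating mean occupancy from unrepresentative nonprobability samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mean occupancy from unrepresentative nonprobability samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuadjust)
```

## The inference problem

Biodiversity monitoring is usually descriptive inference: estimate some
summary of a variable of interest across a whole landscape — here, the
proportion of 1-km grid squares a plant species occupies (mean occupancy
$\bar{y}_N$) — from observations at a sample of squares. Opportunistic
citizen-science records are a *nonprobability* sample: nobody controlled
which squares were visited, and the inclusion probabilities are unknown.
Recorders tend to favour accessible, low-lying or protected ground, so
sampled squares differ systematically from the rest of the landscape.

The damage this does is captured exactly by the data defect correlation
(ddc) $\hat\rho_{R,y}$, the population Pearson correlation between the
sample-inclusion indicator $R$ and the outcome $y$ across all $N$ units:

$$\bar{y}_n - \bar{y}_N \;=\; \hat\rho_{R,y}\,\sqrt{\tfrac{N-n}{n}}\;\sigma_y ,$$

with $\sigma_y$ the population (1/$N$-convention) standard deviation. The
identity is algebraic — `meng_error_decomposition()` verifies it to
floating-point precision on every frame, and that check is the package's
primary oracle for the ddc code. A simple random sample has ddc of order
$N^{-1/2}$; anything materially larger means the naive sample mean is
appreciably biased no matter how large $n$ is.

## The estimators

All estimators target $\bar{y}_N$ per time period, and all of the
weighting-based ones are Hájek ratio means
$\sum_{i\in s} y_i w_i / \sum_{i\in s} w_i$ (`weighted_mean()`), which is
invariant to rescaling the weights:

* **Naive** (`naive_mean`): $w_i \equiv 1/n$; the baseline.
* **Design-based** (`unit_weights` with $w_i = 1/p_i$): applicable only
  when true inclusion probabilities exist; on synthetic frames it is the
  gold standard the others are judged against.
* **Quasirandomization** (`estimate_propensity_weights`): pretend the
  sample was drawn probabilistically, fit a binary model of $R$ on
  covariates over the *whole* frame (this is prediction, not inference —
  $R$ is known everywhere), and weight by reciprocal fitted probabilities.
* **Poststratification** (`build_poststrata`,
  `poststratification_weights`): discretize the auxiliaries (elevation
  deciles × protected {0, >0}, giving 20 cells), weight each sampled unit
  by $N_j/n_j$. Weighted cell counts then reproduce the population cell
  counts exactly.
* **Superpopulation modelling** (`superpopulation_estimate`): fit a linear
  regression of $y$ on the auxiliaries on the sampled units, predict the
  nonsampled units, and average
  $(\sum_{i\in s} y_i + \sum_{i\in\bar{s}}\hat{y}_i)/N$.
* **Doubly robust** (`doubly_robust_estimate`):
  $\frac1N\sum_{i\in s} r_i/\hat p_i + \frac1N\sum_{i=1}^{N}\hat y_i$ with
  $r_i = y_i - \hat y_i$; consistent if either component model is right.
* **Subsampling** (`stratified_subsample_mean`): draw a representative
  miniature of the population — with replacement, per stratum,
  proportional to $N_j/N$, total $N/10$ — and take its mean.
* **MRP** (`mrp_estimate`): hierarchical binomial model of cell occupancy
  (logit link, fixed intercept, random intercepts for each discretized
  auxiliary and their interaction), poststratified by population cell
  shares $\sum_j (N_j/N)\theta_j$ per posterior draw.

## The synthetic landscape and what it emulates

`synthetic_config()` + `simulate_landscape()` generate finite populations
with known truth so that every estimator claim in this package is testable
without any external data. The generative model is deliberately minimal:

* **elevation** ~ gamma(shape 1.5, scale 90) — a right-skewed national
  elevation profile in metres;
* **protected_prop** ~ zero-inflated uniform on [0, 1] (60% exact zeros by
  default) — most squares contain no protected land;
* **occupancy**: Bernoulli, logit linear in the z-scored auxiliaries
  (slopes +1.2 elevation, +0.5 protected — an upland shrub that also
  favours protected land);
* **inclusion**: independent Bernoulli per unit (Poisson sampling — the
  real recording process has no fixed sample size), logit linear in the
  z-scored auxiliaries plus `gamma_y` $\times\, y$.

Auxiliaries are standardized before entering the links so coefficient
magnitudes are comparable across configurations. `gamma_y = 0` (the
default) makes occupancy independent of inclusion given the auxiliaries —
missingness at random (MAR) holds *by construction*, and the partial ddc
(`partial_ddc`, computed as the Pearson correlation of the linear-projection
residuals of $R$ and $y$ on the auxiliaries) is zero in expectation.
Nonzero `gamma_y` violates MAR in a controlled, quantifiable way.

The default intercepts were chosen once, by solving for target marginal
rates: period one samples ~43% of units with ddc ≈ −0.12 and true mean
occupancy 0.32; period two samples ~62% with ddc ≈ −0.06 and mean 0.27
(a true decline of about −0.05). Recorders under-visit high ground
(inclusion slope −1.15, then −0.42 as coverage broadens) while occupancy
increases with elevation, so the naive mean *underestimates* occupancy —
the adjustment methods must pull it up. Periods are generated
independently: nothing ties one period's recorder behaviour to the other's.

What the generator does **not** emulate: spatial autocorrelation (units
are exchangeable), measurement error (a sampled occupied square is always
detected), shared recorder identity across periods, and real geography of
any species. Passing tests therefore demonstrate that the estimators are
implemented correctly and behave as the theory predicts *under MAR-style
selection on smooth auxiliary surfaces* — not that any particular real
dataset satisfies those assumptions.

## Numerical and design choices

* **Propensity model**: logistic regression by default — transparent,
  fast, and correctly specified for the generator, which makes
  unbiasedness testable. A probability forest (`model_kind = "forest"`,
  via ranger) is available for non-additive inclusion surfaces; forest
  probabilities are neither calibrated nor truncated beyond the common
  clip. All fitted probabilities are clipped to [1e-6, 1] and the number
  of clipped units is recorded on the fit.
* **Decile cuts** use the population distribution (not the sample's),
  left-open/right-closed with the lowest value included; tied cut points
  collapse bins with a message.
* **Empty-but-populated poststrata** would make $N_j/n_j$ undefined; the
  default merges the offending elevation bin into its nearest sampled
  neighbour within the same protected class, iterating until no such cell
  remains. With `collapse_empty = FALSE` the weight constructor refuses
  instead of guessing. MRP needs no collapsing — partial pooling gives
  empty cells finite shrunken estimates.
* **Linear outcome model on a binary response**: predictions are *not*
  clipped to [0, 1]. Clipping would break the exact identity between the
  prediction form and the implied-weight Hájek form
  ($w_i = 1 + t_{x,\bar s}^\top (X_s^\top X_s)^{-1} x_i$, which calibrates
  to $\sum w = N$ with an intercept). Estimates outside [0, 1] are
  reported as-is with a warning.
* **Doubly robust second term** sums $\hat y_i$ over all $N$ units,
  residuals added only over the sample.
* **Subsample allocation** uses largest-remainder rounding so the total
  equals the requested size exactly.
* **Bootstrap**: sampled units are resampled i.i.d. with replacement
  (the nonsampled population held fixed) and the *entire* estimator —
  including its model fits — is recomputed per replicate; percentile
  intervals come from the replicate order statistics. Replicates that fail
  are dropped and counted, with a 5% failure ceiling. Periods are
  bootstrapped independently; the trend interval differences
  independently indexed replicates.
* **Analytic intervals** use the with-replacement linearization variance
  of the Hájek mean, $\tfrac{n}{n-1}\sum_i z_i^2$ with
  $z_i = w_i(y_i-\hat\mu)/\sum w$; no finite-population correction is
  applied, so intervals are mildly conservative at large sampling
  fractions. With equal weights this is the binomial-proportion formula.
* **MRP**: fitted with JAGS, 5 chains × 1000 kept iterations after 500
  adaptation and 500 burn-in updates per chain; weakly informative
  priors — normal(0, sd 2) on the fixed intercept, half-normal(0, 1) on
  the random-intercept scales. The fixed intercept and random-intercept
  means are additively aliased (only their sums enter the likelihood), so
  convergence is diagnosed with split-$\hat{R}$ (< 1.05) on the
  *identified* quantities: the poststratified mean and every cell
  probability. Non-convergence attaches a note and warns rather than
  failing silently. The trend uses posterior draws, not a bootstrap.
* **Normal trend interval**: point $\pm\,z_{0.975}\sqrt{var_1 + var_2}$.

## Validation scale

The test-suite simulations are sized to finish on a single CPU while
keeping Monte-Carlo error well below the effects being measured:
unbiasedness and double robustness at $N = 5000$ with 500 replicate
inclusion draws (judged at 3 Monte-Carlo standard errors, with occupancy
redrawn per replicate so each scenario is compared with its own
population's mean); bias ordering of all seven estimators at $N = 5000$
over 200 regenerated landscapes (MRP at 2 chains × 400 iterations there —
posterior means are stable far earlier than full-length chains); interval
coverage under a deliberate MAR violation (`gamma_y = -1.5`) at
$N = 2000$ over 200 worlds; identity checks up to $N = 10^5$.
`scripts/acceptance.R` reruns the full pipeline on a fresh $N = 20000$
landscape with $B = 200$ bootstrap replicates and MRP at its defaults.

## Known limitations

* Unbiasedness under adjustment is only as good as the MAR assumption;
  with `gamma_y` away from zero every auxiliary-based method stays biased
  and — as the coverage tests demonstrate — 95% intervals cover the truth
  in far fewer than 95% of worlds. Residual bias should be assumed, and
  reported, in any real application.
* The superpopulation model is linear; its implied weights can be
  negative, which is expected regression-calibration behaviour but means
  they are not usable as frequency weights.
* No unit-level weights exist for the doubly robust estimator or MRP in
  this package, so their effect on auxiliary distributions cannot be
  displayed via `binned_relative_frequency_comparison()`; subsampling is
  compared through the subsample's own empirical distribution instead.
* The analytic poststratification interval ignores the
  finite-population correction and the estimation of the cell weights.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(N = 10000, seed = 1)
frame <- simulate_landscape(cfg)

meng_error_decomposition(frame, period = 1)

result <- run_analysis(analysis_config(frame = frame, B = 200, seed = 1))
result
write_report(result, "occupancy-report")
```
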