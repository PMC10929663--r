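test_that("naive and Hajek weighted means match enumeration and are scale invariant", {
  fr <- make_frame(c(1, 0, 1, 1), R = c(1, 1, 1, 1))
  expect_equal(naive_mean(fr, 1)$point, 0.75)
  fr2 <- make_frame(c(1, 0), R = c(1, 1))
  expect_equal(naive_mean(fr2, 1, interval = "none")$point, 0.5)

  # design-based example: sampled units 1,2 with p = (0.5, 1) -> (2, 1)
  fr3 <- make_frame(c(1, 0, 1, 1), R = c(1, 1, 0, 0))
  w <- unit_weights(fr3$unit_id[1:2], c(2, 1), method = "design")
  expect_equal(weighted_mean(fr3, 1, w), 2 / 3)

  # constant weights collapse to the naive mean; rescaling changes nothing
  fr4 <- default_frame(N = 400, seed = 10)
  s <- which(fr4$R_p1 == 1)
  w_const <- unit_weights(fr4$unit_id[s], rep(3.7, length(s)),
                          method = "design")
  expect_equal(weighted_mean(fr4, 1, w_const), naive_mean(fr4, 1)$point)
  w7 <- unit_weights(fr4$unit_id[s], 7 * runif(length(s)) + 1,
                     method = "design")
  w1 <- unit_weights(w7$unit_ids, w7$w / 7, method = "design")
  expect_equal(weighted_mean(fr4, 1, w7), weighted_mean(fr4, 1, w1))
})

test_that("weight containers validate their invariants", {
  expect_error(unit_weights("a", -1, method = "design"), "positive")
  expect_silent(unit_weights("a", -1, method = "superpopulation"))
  expect_error(unit_weights(c("a", "b"), 1), "length")
  fr <- make_frame(c(1, 0, 1), R = c(1, 1, 0))
  w_bad <- unit_weights("u0003", 1, method = "design")
  expect_error(weighted_mean(fr, 1, w_bad), "exactly the sampled units")
})

test_that("intercept-only propensity model reproduces the naive mean", {
  fr <- default_frame(N = 800, seed = 4)
  pw <- estimate_propensity_weights(fr, 1, covariates = character(0))
  expect_equal(unname(pw$fit$p_hat),
               rep(mean(fr$R_p1), nrow(fr)), tolerance = 1e-10)
  expect_equal(weighted_mean(fr, 1, pw$weights), naive_mean(fr, 1)$point)
})

test_that("propensity model surface: constant inclusion is rejected, probabilities clipped", {
  fr <- make_frame(c(1, 0, 1, 0), R = c(1, 1, 1, 1))
  expect_error(estimate_propensity_weights(fr, 1), "constant")
  fr2 <- default_frame(N = 600, seed = 6)
  pw <- estimate_propensity_weights(fr2, 1)
  expect_true(all(pw$fit$p_hat >= 1e-6 & pw$fit$p_hat <= 1))
  expect_length(pw$fit$p_hat, nrow(fr2))
  expect_true(all(pw$weights$w > 0))
})

test_that("design-based weighting with the true probabilities is unbiased over replicate inclusions", {
  cfg <- synthetic_config(N = 4000, seed = 15, n_periods = 1)
  fr0 <- generate_population(cfg)
  truth <- mean(fr0$y_p1)
  set.seed(16)
  ests <- replicate(500, {
    fr <- apply_inclusion_mechanism(fr0, cfg)
    s <- which(fr$R_p1 == 1)
    w <- unit_weights(fr$unit_id[s], 1 / fr$p_true_p1[s], method = "design")
    weighted_mean(fr, 1, w)
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * mc_se)
})

test_that("poststrata cross the discretized auxiliaries with exact counts", {
  fr <- default_frame(N = 2000, seed = 20)
  st <- build_poststrata(fr, 1)
  # both protected classes present: 10 x 2 = 20 strata
  expect_equal(nrow(st$table), 20L)
  expect_equal(sum(st$table$Nj), nrow(fr))
  expect_equal(sum(st$table$nj), sum(fr$R_p1))
  expect_true(all(table(st$assignment) == st$table$Nj))

  # a single stratum (one elevation bin via 1 cut, all unprotected)
  fr1 <- make_frame(rbinom(50, 1, 0.5), R = rbinom(50, 1, 0.6),
                    elevation = runif(50))
  st1 <- build_poststrata(fr1, 1, elevation_bins = 1)
  expect_equal(nrow(st1$table), 1L)
  expect_equal(st1$table$Nj, 50L)
  expect_equal(st1$table$nj, sum(fr1$R_p1))
})

test_that("poststratification weights calibrate to stratum counts and reproduce cell-mean algebra", {
  # two strata, (N1=100, n1=10, ybar1=0.8), (N2=100, n2=90, ybar2=0.2)
  set.seed(30)
  fr <- make_two_stratum_frame(100, 10, 0.8, 100, 90, 0.2)
  st <- build_poststrata(fr, 1, elevation_bins = 2)
  w <- poststratification_weights(st, fr)
  expect_equal(weighted_mean(fr, 1, w), 0.5)
  expect_equal(sum(w$w), 200)
  # per-stratum calibration: weighted count equals Nj exactly
  s <- which(fr$R_p1 == 1)
  for (j in st$table$stratum) {
    in_j <- st$assignment[s] == j
    expect_equal(sum(w$w[match(fr$unit_id[s][in_j], w$unit_ids)]),
                 st$table$Nj[j])
  }

  # one stratum: poststratified estimate is the naive mean
  fr1 <- make_frame(rbinom(80, 1, 0.4), R = rbinom(80, 1, 0.5),
                    elevation = runif(80))
  expect_equal(poststratification_estimate(fr1, 1,
                 strata = build_poststrata(fr1, 1, elevation_bins = 1)),
               naive_mean(fr1, 1)$point)
})

test_that("poststratification is unbiased when inclusion depends only on the strata", {
  # inclusion probability a function of the stratum label alone
  set.seed(40)
  N <- 3000
  elev <- rgamma(N, 2, scale = 50)
  prot <- ifelse(runif(N) < 0.5, 0, runif(N))
  y <- rbinom(N, 1, plogis(-0.5 + as.numeric(scale(elev))))
  fr0 <- make_frame(y, elevation = elev, protected = prot)
  st_pop <- build_poststrata(
    structure(cbind(fr0, R_p1 = 1L), class = class(fr0), n_periods = 1L), 1)
  p_by_stratum <- seq(0.1, 0.9, length.out = nrow(st_pop$table))
  p_unit <- p_by_stratum[st_pop$assignment]
  truth <- mean(y)
  ests <- replicate(400, {
    fr <- fr0
    fr$R_p1 <- rbinom(N, 1, p_unit)
    poststratification_estimate(fr, 1)
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * mc_se)
})

test_that("empty-but-populated strata collapse into neighbours or error", {
  set.seed(50)
  fr <- default_frame(N = 1500, seed = 51)
  # force an empty cell: unsample every sampled unit in the top elevation decile
  cutpt <- quantile(fr$elevation, 0.9)
  fr$R_p1[fr$elevation > cutpt] <- 0L
  expect_message(st <- build_poststrata(fr, 1), "collapsing")
  expect_true(all(st$table$nj[st$table$Nj > 0] > 0))
  expect_equal(sum(st$table$Nj), nrow(fr))
  st_raw <- suppressMessages(build_poststrata(fr, 1, collapse_empty = FALSE))
  expect_error(poststratification_weights(st_raw, fr), "no sampled units")
})

test_that("superpopulation estimator: intercept-only equals naive, exact linear outcome recovers truth", {
  fr <- default_frame(N = 600, seed = 60)
  sp0 <- superpopulation_estimate(fr, 1, predictors = character(0))
  expect_equal(sp0$estimate, naive_mean(fr, 1)$point)

  # y exactly linear in a predictor: zero residuals, estimate = truth
  set.seed(61)
  N <- 200
  x <- runif(N)
  y <- 0.2 + 0.5 * x  # continuous outcome, exactly linear
  fr_lin <- make_frame(y, R = rbinom(N, 1, 0.5), elevation = x)
  sp <- superpopulation_estimate(fr_lin, 1, predictors = "elevation")
  expect_equal(sp$estimate, mean(y), tolerance = 1e-12)
  expect_equal(max(abs(sp$fit$residuals)), 0, tolerance = 1e-12)
})

test_that("saturated superpopulation model equals poststratification", {
  set.seed(70)
  fr <- default_frame(N = 200, seed = 71)
  st <- build_poststrata(fr, 1, elevation_bins = 4)
  fr$stratum_f <- factor(st$assignment)
  # drop population-only factor levels absent from the sample would break the
  # fit only if a stratum has Nj>0, nj=0; collapse guarantees it does not
  sp <- superpopulation_estimate(fr, 1, predictors = "stratum_f")
  expect_equal(sp$estimate, poststratification_estimate(fr, 1, strata = st),
               tolerance = 1e-12)
})

test_that("rank-deficient superpopulation designs fail loudly, naming columns", {
  fr <- default_frame(N = 300, seed = 80)
  fr$elev_copy <- fr$elevation
  expect_error(superpopulation_estimate(fr, 1,
                 predictors = c("elevation", "elev_copy")),
               "elev_copy")
})

test_that("implied superpopulation weights reproduce the prediction-form estimate and calibrate to N", {
  for (seed in c(90, 91, 92)) {
    fr <- default_frame(N = 1000, seed = seed)
    sp <- superpopulation_estimate(fr, 1)
    w <- superpopulation_implied_weights(sp$fit, fr)
    expect_lt(abs(weighted_mean(fr, 1, w) - sp$estimate), 1e-10)
    expect_lt(abs(sum(w$w) - nrow(fr)), 1e-8)
  }
  # intercept-only fit: implied weights all equal
  fr <- default_frame(N = 400, seed = 93)
  sp0 <- superpopulation_estimate(fr, 1, predictors = character(0))
  w0 <- superpopulation_implied_weights(sp0$fit, fr)
  expect_equal(max(w0$w) - min(w0$w), 0, tolerance = 1e-10)
})

test_that("doubly robust estimate collapses to the superpopulation estimate when residuals vanish", {
  set.seed(100)
  N <- 300
  x <- runif(N)
  y <- 0.1 + 0.6 * x
  R <- rbinom(N, 1, 0.5)
  fr <- make_frame(y, R = R, elevation = x)
  sp <- superpopulation_estimate(fr, 1, predictors = "elevation")
  pf <- estimate_propensity_weights(fr, 1, covariates = "elevation")$fit
  expect_equal(doubly_robust_estimate(fr, 1, pf, sp$fit), sp$estimate,
               tolerance = 1e-10)
})

test_that("subsample strata shares match Nj/N up to largest-remainder rounding and single-stratum expectation is the naive mean", {
  fr <- default_frame(N = 2000, seed = 110)
  st <- build_poststrata(fr, 1)
  m <- stratified_subsample_mean(fr, 1, st, size = 200, seed = 1)
  alloc <- attr(m, "allocation")
  expect_equal(sum(alloc), 200)
  expect_true(all(abs(alloc - 200 * st$table$Nj / nrow(fr)) <= 1))

  fr1 <- make_frame(rbinom(100, 1, 0.5), R = rbinom(100, 1, 0.5),
                    elevation = runif(100))
  st1 <- build_poststrata(fr1, 1, elevation_bins = 1)
  reps <- stratified_subsample_mean(fr1, 1, st1, size = 50, seed = 2,
                                    n_replicates = 800)
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - naive_mean(fr1, 1)$point), 4 * se)
})
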