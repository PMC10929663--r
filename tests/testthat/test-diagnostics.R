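test_that("ddc matches hand enumeration and its boundary cases", {
  fr <- make_frame(c(1, 0, 1, 1), R = c(1, 1, 0, 0))
  # cov = -0.125, sd_R = 0.5, sd_y = 0.43301 (1/N convention)
  expect_equal(data_defect_correlation(fr, 1), -0.57735, tolerance = 1e-5)

  # perfect preferential sampling: R == y
  fr2 <- make_frame(c(1, 0, 1, 0), R = c(1, 0, 1, 0))
  expect_equal(data_defect_correlation(fr2, 1), 1)

  expect_error(data_defect_correlation(make_frame(c(1, 1), R = c(1, 0)), 1),
               "zero variance")
  expect_error(data_defect_correlation(make_frame(c(1, 0), R = c(1, 1)), 1),
               "zero variance")
})

test_that("ddc is invariant to unit relabeling and antisymmetric under y -> 1 - y", {
  set.seed(300)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.4); R <- rbinom(60, 1, 0.5)
    if (var(y) == 0 || var(R) == 0) next
    fr <- make_frame(y, R = R)
    perm <- sample(60)
    fr_perm <- make_frame(y[perm], R = R[perm])
    expect_equal(data_defect_correlation(fr_perm, 1),
                 data_defect_correlation(fr, 1))
    fr_flip <- make_frame(1 - y, R = R)
    expect_equal(data_defect_correlation(fr_flip, 1),
                 -data_defect_correlation(fr, 1))
  }
})

test_that("partial ddc equals marginal ddc when auxiliaries are uninformative, and detects MAR violations", {
  # auxiliaries uncorrelated with R and y: projection leaves residuals as-is
  set.seed(301)
  y <- rbinom(500, 1, 0.5); R <- rbinom(500, 1, 0.5)
  aux <- runif(500)
  fr <- make_frame(y, R = R, elevation = aux, protected = runif(500))
  # regress out an unrelated auxiliary only changes the correlation at
  # sampling-noise order; with orthogonalized auxiliaries it is exact
  aux_o <- residuals(lm(aux ~ y + R))
  prot_o <- residuals(lm(runif(500) ~ y + R))
  fr_o <- make_frame(y, R = R, elevation = aux_o, protected = prot_o)
  expect_equal(partial_ddc(fr_o, 1), data_defect_correlation(fr_o, 1),
               tolerance = 1e-9)

  # MAR by construction: partial ddc ~ 0 while marginal ddc is not
  cfg <- synthetic_config(N = 6000, seed = 302, gamma_y = 0, n_periods = 1)
  set.seed(303)
  fr0 <- generate_population(cfg)
  pddc <- replicate(30, partial_ddc(apply_inclusion_mechanism(fr0, cfg), 1))
  mddc <- replicate(30, data_defect_correlation(
    apply_inclusion_mechanism(fr0, cfg), 1))
  expect_lt(abs(mean(pddc)), 3 * sd(pddc) / sqrt(30) + 0.01)
  expect_lt(mean(mddc) + 3 * sd(mddc) / sqrt(30), -0.02)

  # strongly negative direct effect of y on inclusion: partial ddc < 0
  cfg_v <- synthetic_config(N = 6000, seed = 304, gamma_y = -2,
                            n_periods = 1)
  set.seed(305)
  fr0v <- generate_population(cfg_v)
  pddc_v <- replicate(30, partial_ddc(apply_inclusion_mechanism(fr0v, cfg_v),
                                      1))
  expect_lt(mean(pddc_v) + 3 * sd(pddc_v) / sqrt(30), 0)
})

test_that("partial ddc rejects collinear auxiliaries", {
  fr <- default_frame(N = 200, seed = 306)
  fr$elev_copy <- fr$elevation
  expect_error(partial_ddc(fr, 1, auxiliaries = c("elevation", "elev_copy")),
               "collinear")
})

test_that("the ddc error identity holds exactly", {
  # hand-enumerated case: error = 0.5 - 0.75 = -0.25
  fr <- make_frame(c(1, 0, 1, 1), R = c(1, 1, 0, 0))
  rep1 <- meng_error_decomposition(fr, 1)
  expect_equal(rep1$naive_error, -0.25)
  expect_equal(rep1$ddc * rep1$quantity_factor * rep1$sigma_y, -0.25,
               tolerance = 1e-12)
  expect_lt(abs(rep1$identity_residual), 1e-12)

  # identity residual stays at floating-point scale on random frames
  set.seed(310)
  for (i in 1:10) {
    N <- sample(20:2000, 1)
    y <- rbinom(N, 1, runif(1, 0.1, 0.9))
    R <- rbinom(N, 1, runif(1, 0.1, 0.9))
    if (var(y) == 0 || var(R) == 0 || sum(R) %in% c(0, N)) next
    expect_lt(abs(meng_error_decomposition(make_frame(y, R = R),
                                           1)$identity_residual), 1e-12)
  }

  # near-census limit: error shrinks toward zero
  y <- rbinom(1000, 1, 0.5)
  R <- rep(1L, 1000); R[1:3] <- 0L
  expect_lt(abs(meng_error_decomposition(make_frame(y, R = R),
                                         1)$naive_error), 0.01)
  expect_error(meng_error_decomposition(make_frame(y, R = rep(1L, 1000)), 1),
               "n < N")
})

test_that("binned frequency vectors are proper distributions with sensible MAEs", {
  fr <- default_frame(N = 2000, seed = 320)
  pw <- estimate_propensity_weights(fr, 1)
  bc <- binned_relative_frequency_comparison(fr, 1, "elevation",
                                             weights = pw$weights)
  expect_equal(sum(bc$pop_freq), 1, tolerance = 1e-9)
  expect_equal(sum(bc$raw_freq), 1, tolerance = 1e-9)
  expect_equal(sum(bc$weighted_freq), 1, tolerance = 1e-9)
  expect_true(all(bc$pop_freq >= 0 & bc$raw_freq >= 0 &
                    bc$weighted_freq >= 0))
  expect_gte(bc$mae_raw, 0)
  expect_length(bc$edges, 51)

  # sample = full population: raw MAE is exactly zero
  fr_all <- fr
  fr_all$R_p1 <- 1L
  w_all <- unit_weights(fr_all$unit_id, rep(1, nrow(fr_all)),
                        method = "design")
  bc_all <- binned_relative_frequency_comparison(fr_all, 1, "elevation",
                                                 weights = w_all)
  expect_equal(bc_all$mae_raw, 0)
  expect_equal(bc_all$mae_weighted, 0)

  expect_error(binned_relative_frequency_comparison(
    make_frame(c(1, 0), R = c(1, 0), elevation = c(2, 2)), 1, "elevation",
    subsample = 1L), "constant")
})

test_that("poststratification weights zero out the MAE at stratum resolution", {
  # auxiliary measured at the resolution of the stratifying variable itself:
  # calibration forces an exact match
  set.seed(330)
  fr <- make_two_stratum_frame(120, 30, 0.6, 120, 80, 0.3)
  st <- build_poststrata(fr, 1, elevation_bins = 2)
  w <- poststratification_weights(st, fr)
  fr$stratum_code <- as.numeric(st$assignment)
  bc <- binned_relative_frequency_comparison(fr, 1, "stratum_code",
                                             weights = w, bins = 2)
  expect_equal(bc$mae_weighted, 0, tolerance = 1e-12)
  expect_gt(bc$mae_raw, 0)
})
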