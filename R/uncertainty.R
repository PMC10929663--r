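# single-number point estimate for a named method; used by the bootstrap
# (which must refit everything per replicate) and by the pipeline
point_estimate <- function(frame, period, method,
                           covariates = c("elevation", "protected_prop"),
                           model_kind = "logistic", clip = 1e-6,
                           elevation_bins = 10L, subsample_size = NULL) {
  switch(method,
    naive = {
      s <- sampled_index(frame, period)
      mean(period_column(frame, "y", period)[s])
    },
    design = {
      s <- sampled_index(frame, period)
      p <- period_column(frame, "p_true", period)[s]
      w <- unit_weights(frame$unit_id[s], 1 / p, method = "design",
                        normalization = "N")
      weighted_mean(frame, period, w)
    },
    quasirandomization = quasirandomization_estimate(
      frame, period, model_kind = model_kind, covariates = covariates,
      clip = clip),
    poststratification = poststratification_estimate(
      frame, period, elevation_bins = elevation_bins),
    superpopulation = superpopulation_estimate(
      frame, period, predictors = covariates)$estimate,
    doubly_robust = {
      pf <- estimate_propensity_weights(frame, period,
                                        model_kind = model_kind,
                                        covariates = covariates,
                                        clip = clip)$fit
      sp <- superpopulation_estimate(frame, period,
                                     predictors = covariates)$fit
      doubly_robust_estimate(frame, period, pf, sp)
    },
    subsampling = {
      strata <- build_poststrata(frame, period,
                                 elevation_bins = elevation_bins)
      stratified_subsample_mean(frame, period, strata,
                                size = subsample_size)[1]
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Bootstrap percentile interval for an adjustment estimator
#'
#' Resamples the sampled units with replacement (`n` draws per replicate,
#' the nonsampled population held fixed), recomputes the full estimator —
#' including refitting its inclusion and/or outcome models — on each of the
#' `B` replicates, and returns the central percentile interval of the
#' replicate distribution. A replicate in which the estimator fails (e.g. a
#' degenerate refit) is dropped and counted; more than 5% failures aborts.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param estimator Method name: one of `"naive"`, `"quasirandomization"`,
#'   `"poststratification"`, `"superpopulation"`, `"doubly_robust"`,
#'   `"subsampling"`, `"design"`.
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional seed; fixing it makes the interval reproducible.
#' @param ... Estimator options passed through (`covariates`,
#'   `model_kind`, `clip`, `elevation_bins`, `subsample_size`).
#' @return An [estimate_result()] whose `draws` are the replicate
#'   estimates; extra elements `B` and `n_failed` record replicate
#'   bookkeeping.
#' @export
bootstrap_percentile_interval <- function(frame, period = 1L, estimator,
                                          B = 1000L, level = 0.95,
                                          seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  R <- period_column(frame, "R", period)
  s <- which(R == 1L)
  n <- length(s)
  if (n < 2L) stop("need at least 2 sampled units to bootstrap",
                   call. = FALSE)
  point <- point_estimate(frame, period, estimator, ...)
  nonsampled <- frame[R == 0L, , drop = FALSE]

  reps <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(B)) {
    draw <- s[sample.int(n, n, replace = TRUE)]
    boot_frame <- rbind(nonsampled, frame[draw, , drop = FALSE])
    boot_frame$unit_id <- sprintf("b%07d", seq_len(nrow(boot_frame)))
    attributes(boot_frame)$n_periods <- attr(frame, "n_periods")
    class(boot_frame) <- class(frame)
    est <- tryCatch(point_estimate(boot_frame, period, estimator, ...),
                    error = function(e) NA_real_)
    if (is.na(est)) n_failed <- n_failed + 1L else reps <- c(reps, est)
  }
  if (n_failed > 0.05 * B)
    stop(sprintf("%d of %d bootstrap replicates failed (> 5%%)", n_failed, B),
         call. = FALSE)

  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  res <- estimate_result(estimator, period, point, ci[1], ci[2],
                         "percentile-bootstrap", draws = reps,
                         se = stats::sd(reps))
  res$B <- B
  res$n_failed <- n_failed
  res
}

#' Analytic (linearization) confidence interval for a weighted mean
#'
#' The survey-style with-replacement linearization interval for the Hajek
#' ratio mean: with influence values
#' \eqn{z_i = w_i (y_i - \hat{\mu}) / \sum w}, the variance estimate is
#' \eqn{\frac{n}{n-1} \sum_i z_i^2} and the interval is
#' \eqn{\hat{\mu} \pm z_{\alpha/2} \cdot SE}. With equal weights this
#' reduces to the binomial-proportion standard error
#' \eqn{\sqrt{\hat{p}(1-\hat{p})/(n-1)}}, which is what the naive estimate
#' gets.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param weights A [unit_weights()] object, or `NULL` for the unweighted
#'   (naive) case.
#' @param level Confidence level.
#' @return A list with `point`, `se`, `lo`, `hi`.
#' @export
analytic_interval <- function(frame, period = 1L, weights = NULL,
                              level = 0.95) {
  s <- sampled_index(frame, period)
  n <- length(s)
  if (n < 2L) stop("need at least 2 sampled units", call. = FALSE)
  y <- period_column(frame, "y", period)[s]
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    stopifnot(inherits(weights, "unit_weights"))
    w <- weights$w[match(frame$unit_id[s], weights$unit_ids)]
    if (anyNA(w)) stop("weights must cover every sampled unit", call. = FALSE)
  }
  total <- sum(w)
  point <- sum(w * y) / total
  z <- w * (y - point) / total
  se <- sqrt(n / (n - 1) * sum(z^2))
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(point = point, se = se, lo = point - q * se, hi = point + q * se)
}

#' Between-period trend in mean occupancy, with interval
#'
#' The trend is the difference between the two per-period estimates of the
#' same method, \eqn{\bar{y}_2 - \bar{y}_1}. Methods that produce a
#' replicate distribution (bootstrap replicates or posterior draws) get a
#' percentile interval of the independently indexed replicate differences;
#' methods with only a standard error get the normal approximation
#' \eqn{\pm z_{\alpha/2}\sqrt{\mathrm{var}_1 + \mathrm{var}_2}}.
#'
#' @param result1,result2 [estimate_result()] objects for periods one and
#'   two, produced by the same method.
#' @param mode `"percentile"` (needs `draws` in both results) or
#'   `"normal"` (needs `se` in both).
#' @param level Confidence level.
#' @return A `trend_result` list: `method`, `point`, `lo`, `hi`,
#'   `interval_method`.
#' @export
trend_with_interval <- function(result1, result2,
                                mode = c("percentile", "normal"),
                                level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(result1, "estimate_result"),
            inherits(result2, "estimate_result"))
  if (!identical(result1$method, result2$method))
    stop("trend requires both periods estimated by the same method",
         call. = FALSE)
  point <- result2$point - result1$point
  if (mode == "percentile") {
    if (is.null(result1$draws) || is.null(result2$draws))
      stop("percentile mode needs replicate distributions in both periods",
           call. = FALSE)
    m <- min(length(result1$draws), length(result2$draws))
    diffs <- result2$draws[seq_len(m)] - result1$draws[seq_len(m)]
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha)))
  } else {
    if (is.null(result1$se) || is.null(result2$se))
      stop("normal mode needs standard errors in both periods",
           call. = FALSE)
    q <- stats::qnorm(1 - (1 - level) / 2)
    half <- q * sqrt(result1$se^2 + result2$se^2)
    ci <- c(point - half, point + half)
  }
  structure(list(method = result1$method, point = point,
                 lo = ci[1], hi = ci[2], interval_method = mode),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("%s trend: %.4f  [%.4f, %.4f] (%s)\n", x$method, x$point,
              x$lo, x$hi, x$interval_method))
  invisible(x)
}
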