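#' Data defect correlation (ddc)
#'
#' The population Pearson correlation between sample inclusion and the
#' variable of interest, computed across all `N` units with the population
#' (1/N) moment convention. A representative sample has ddc near zero (a
#' simple random sample's ddc is of order \eqn{N^{-1/2}}); preferential
#' sampling of occupied or unoccupied units pushes it away from zero, and
#' with it the naive sample mean away from the truth.
#'
#' @param frame A `population_frame` with realized inclusion.
#' @param period Period index.
#' @return A correlation in \[-1, 1\].
#' @export
data_defect_correlation <- function(frame, period = 1L) {
  R <- period_column(frame, "R", period)
  y <- period_column(frame, "y", period)
  if (stats::var(R) == 0 || stats::var(y) == 0)
    stop("ddc undefined: inclusion or occupancy has zero variance",
         call. = FALSE)
  # correlation is identical under 1/N and 1/(N-1) conventions
  stats::cor(R, y)
}

#' Partial data defect correlation given the auxiliaries
#'
#' The Pearson correlation between the residuals of linear projections of
#' the inclusion indicator and the outcome on the auxiliary variables
#' (with intercept), over all `N` units. Under
#' missing-at-random-given-auxiliaries (and links well approximated
#' linearly) it is near zero even when the marginal ddc is not: the
#' auxiliaries then account for all of the association between inclusion
#' and outcome.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param auxiliaries Column names to condition on.
#' @return A correlation in \[-1, 1\].
#' @export
partial_ddc <- function(frame, period = 1L,
                        auxiliaries = c("elevation", "protected_prop")) {
  missing_aux <- setdiff(auxiliaries, names(frame))
  if (length(missing_aux))
    stop("auxiliaries not in frame: ", paste(missing_aux, collapse = ", "),
         call. = FALSE)
  R <- period_column(frame, "R", period)
  y <- period_column(frame, "y", period)
  X <- stats::model.matrix(stats::reformulate(auxiliaries),
                           data = frame[, auxiliaries, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("auxiliaries are collinear; partial correlation undefined",
         call. = FALSE)
  r_R <- stats::residuals(stats::lm.fit(X, R))
  r_y <- stats::residuals(stats::lm.fit(X, y))
  if (stats::var(r_R) == 0 || stats::var(r_y) == 0)
    stop("partial ddc undefined: a residual vector is constant",
         call. = FALSE)
  stats::cor(r_R, r_y)
}

#' Error decomposition of the naive sample mean
#'
#' Decomposes the naive estimator's error exactly as
#' \deqn{\bar{y}_n - \bar{y}_N = \hat{\rho}_{R,y} \times
#'   \sqrt{\frac{N-n}{n}} \times \sigma_y,}
#' the product of the data defect correlation, a data-quantity factor, and
#' the population standard deviation of the outcome (1/N convention). The
#' identity is algebraic — it holds to floating-point precision on any
#' frame — and is the primary correctness oracle for the ddc itself. The
#' report also carries the partial ddc given the auxiliaries when they are
#' present.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @return A `ddc_report` list: `period`, `ddc`, `partial_ddc`,
#'   `naive_error` (\eqn{\bar{y}_n - \bar{y}_N}), the three decomposition
#'   factors, and `identity_residual` (error minus the reconstructed
#'   product).
#' @export
meng_error_decomposition <- function(frame, period = 1L) {
  R <- period_column(frame, "R", period)
  y <- period_column(frame, "y", period)
  N <- length(y)
  n <- sum(R)
  if (n == 0L || n == N)
    stop("decomposition needs 1 <= n < N", call. = FALSE)
  ddc <- data_defect_correlation(frame, period)
  sigma_y <- stats::sd(y) * sqrt((N - 1) / N)  # population (1/N) SD
  quantity <- sqrt((N - n) / n)
  naive_error <- mean(y[R == 1L]) - mean(y)
  pddc <- if (all(c("elevation", "protected_prop") %in% names(frame)))
    tryCatch(partial_ddc(frame, period), error = function(e) NA_real_)
  else NA_real_
  structure(list(period = period,
                 ddc = ddc,
                 partial_ddc = pddc,
                 naive_error = naive_error,
                 quantity_factor = quantity,
                 sigma_y = sigma_y,
                 identity_residual = naive_error - ddc * quantity * sigma_y,
                 N = N, n = n),
            class = "ddc_report")
}

#' @export
print.ddc_report <- function(x, ...) {
  cat(sprintf("Period %s: n/N = %d/%d (%.1f%% sampled)\n", x$period, x$n,
              x$N, 100 * x$n / x$N))
  cat(sprintf("  ddc = %.4f  partial ddc = %.4f\n", x$ddc, x$partial_ddc))
  cat(sprintf("  naive error = %.4f = ddc x sqrt((N-n)/n) x sd(y) = %.4f x %.4f x %.4f (residual %.1e)\n",
              x$naive_error, x$ddc, x$quantity_factor, x$sigma_y,
              x$identity_residual))
  invisible(x)
}

#' @export
as.data.frame.ddc_report <- function(x, ...) {
  data.frame(period = x$period, N = x$N, n = x$n, ddc = x$ddc,
             partial_ddc = x$partial_ddc, naive_error = x$naive_error,
             quantity_factor = x$quantity_factor, sigma_y = x$sigma_y,
             identity_residual = x$identity_residual)
}

#' Binned auxiliary-distribution comparison
#'
#' Splits an auxiliary variable into equal-width bins spanning its
#' population range (50 by default, top bin right-closed so the maximum is
#' counted) and compares three relative-frequency distributions over the
#' bins: the population (\eqn{N_k/N}), the raw sample (\eqn{n_k/n}), and
#' the weighted sample (\eqn{\sum_{i \in k} w_i / \sum_{i \in s} w_i}) —
#' or, for subsampling, the subsample's own distribution. Agreement is
#' summarized by the mean absolute error (MAE) of the sample frequencies
#' against the population frequencies; a smaller weighted MAE than raw MAE
#' means the adjustment pulled the auxiliary's sample distribution closer
#' to the population.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param auxiliary Auxiliary column name.
#' @param weights Optional [unit_weights()] for the weighted comparison.
#' @param subsample Optional integer vector of row indices (a stratified
#'   subsample, possibly with repeats) whose empirical distribution plays
#'   the role of the weighted sample.
#' @param bins Number of equal-width bins.
#' @return A `binned_comparison` with the bin edges, the three frequency
#'   vectors, `mae_raw` and `mae_weighted`.
#' @export
binned_relative_frequency_comparison <- function(frame, period = 1L,
                                                 auxiliary = "elevation",
                                                 weights = NULL,
                                                 subsample = NULL,
                                                 bins = 50L) {
  x <- frame[[auxiliary]]
  if (is.null(x)) stop("no column `", auxiliary, "` in frame", call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0)
    stop("auxiliary is constant: zero-width bins", call. = FALSE)
  if (is.null(weights) && is.null(subsample))
    stop("supply `weights` or a `subsample`", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin_of <- function(v) {
    b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = bins)
  }

  s <- sampled_index(frame, period)
  pop_freq <- bin_of(x) / length(x)
  raw_freq <- bin_of(x[s]) / length(s)

  if (!is.null(weights)) {
    stopifnot(inherits(weights, "unit_weights"))
    w <- weights$w[match(frame$unit_id[s], weights$unit_ids)]
    if (anyNA(w))
      stop("weights must cover every sampled unit", call. = FALSE)
    b <- findInterval(x[s], edges, rightmost.closed = TRUE, all.inside = TRUE)
    wt_freq <- as.numeric(tapply(w, factor(b, levels = seq_len(bins)), sum,
                                 default = 0)) / sum(w)
  } else {
    wt_freq <- bin_of(x[subsample]) / length(subsample)
  }

  structure(list(auxiliary = auxiliary,
                 period = period,
                 edges = edges,
                 pop_freq = pop_freq,
                 raw_freq = raw_freq,
                 weighted_freq = wt_freq,
                 mae_raw = mean(abs(raw_freq - pop_freq)),
                 mae_weighted = mean(abs(wt_freq - pop_freq))),
            class = "binned_comparison")
}

#' @export
print.binned_comparison <- function(x, ...) {
  cat(sprintf("Binned comparison of `%s` (period %s, %d bins)\n",
              x$auxiliary, x$period, length(x$pop_freq)))
  cat(sprintf("  MAE raw sample:      %.5f\n", x$mae_raw))
  cat(sprintf("  MAE adjusted sample: %.5f%s\n", x$mae_weighted,
              if (x$mae_weighted < x$mae_raw)
                "  (adjustment moved the sample closer to the population)"
              else ""))
  invisible(x)
}

#' @export
as.data.frame.binned_comparison <- function(x, ...) {
  bins <- length(x$pop_freq)
  data.frame(auxiliary = x$auxiliary, period = x$period,
             bin = seq_len(bins),
             lower = x$edges[-(bins + 1L)], upper = x$edges[-1L],
             pop_freq = x$pop_freq, raw_freq = x$raw_freq,
             weighted_freq = x$weighted_freq,
             stringsAsFactors = FALSE)
}
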