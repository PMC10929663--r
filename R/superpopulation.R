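#' Superpopulation (regression prediction) estimate of mean occupancy
#'
#' Assumes a linear regression model generates occupancy across the whole
#' population, fits it by least squares on the sampled units, predicts the
#' nonsampled units, and estimates the population mean as
#' \deqn{\bar{y}_{sp} = \left(\sum_{i \in s} y_i + \sum_{i \in \bar{s}} \hat{y}_i\right) / N,}
#' the observed sample total plus the model-predicted total over the rest
#' of the population, divided by the population size.
#'
#' A linear model on a binary outcome is a deliberate choice: it makes the
#' estimator expressible as a Hajek weighted mean with closed-form unit
#' weights (see [superpopulation_implied_weights()]), which in turn lets
#' the method's effect on the auxiliary distributions be inspected.
#' Predictions are not clipped to \[0, 1\], so that weighted-form identity
#' stays exact; if the final estimate falls outside \[0, 1\] a warning is
#' raised and the value reported as-is.
#'
#' @param frame A `population_frame` with realized inclusion.
#' @param period Period index.
#' @param predictors Column names used as model covariates.
#' @return A list with components `fit` (a `superpopulation_fit`: least
#'   squares coefficients, fitted value for every population unit,
#'   residuals on the sampled units, and the design matrices needed for
#'   implied weights) and `estimate` (the proportion).
#' @export
superpopulation_estimate <- function(frame, period = 1L,
                                     predictors = c("elevation",
                                                    "protected_prop")) {
  missing_cov <- setdiff(predictors, names(frame))
  if (length(missing_cov))
    stop("predictors not in frame: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  R <- period_column(frame, "R", period)
  y <- period_column(frame, "y", period)
  s <- which(R == 1L)
  if (length(s) == 0L) stop("no sampled units", call. = FALSE)

  X <- if (length(predictors)) {
    stats::model.matrix(stats::reformulate(predictors),
                        data = frame[, predictors, drop = FALSE])
  } else {
    matrix(1, nrow(frame), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  Xs <- X[s, , drop = FALSE]
  qr_s <- qr(Xs)
  if (qr_s$rank < ncol(Xs)) {
    dropped <- colnames(Xs)[qr_s$pivot[(qr_s$rank + 1L):ncol(Xs)]]
    stop("design matrix on sampled units is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_s, y[s])
  y_hat <- as.numeric(X %*% beta)
  estimate <- (sum(y[s]) + sum(y_hat[-s])) / length(y)
  if (estimate < 0 || estimate > 1)
    warning(sprintf("superpopulation estimate %.4f lies outside [0, 1]; reported as-is",
                    estimate))

  fit <- structure(list(coefficients = beta,
                        y_hat = y_hat,
                        residuals = y[s] - y_hat[s],
                        sampled = s,
                        X = X,
                        predictors = predictors,
                        period = period),
                   class = "superpopulation_fit")
  list(fit = fit, estimate = estimate)
}

#' @export
print.superpopulation_fit <- function(x, ...) {
  cat(sprintf("Superpopulation linear fit (period %s) on %s\n", x$period,
              paste(x$predictors, collapse = " + ")))
  print(x$coefficients)
  invisible(x)
}

#' Implied unit weights of the superpopulation estimator
#'
#' The regression-prediction estimator can be rewritten in the same Hajek
#' weighted form as the design-based estimator: each sampled unit `i`
#' carries the weight
#' \deqn{w_i = 1 + t_{x,\bar{s}}^\top (X_s^\top X_s)^{-1} x_i,}
#' where \eqn{t_{x,\bar{s}}} is the vector of covariate totals over the
#' nonsampled units and \eqn{X_s} the sampled design matrix. With an
#' intercept the weights sum to the population size `N` (regression
#' calibration) and [weighted_mean()] with them reproduces the
#' prediction-form estimate to machine precision. Unlike every other
#' method's weights they may be negative.
#'
#' @param fit A `superpopulation_fit` from [superpopulation_estimate()].
#' @param frame The same frame the fit was computed on.
#' @return A [unit_weights()] object with method `"superpopulation"`.
#' @export
superpopulation_implied_weights <- function(fit, frame) {
  stopifnot(inherits(fit, "superpopulation_fit"))
  X <- fit$X
  s <- fit$sampled
  Xs <- X[s, , drop = FALSE]
  XtX <- crossprod(Xs)
  t_nons <- colSums(X[-s, , drop = FALSE])
  # w_i = 1 + t' (Xs'Xs)^{-1} x_i, solved without forming the inverse
  w <- 1 + as.numeric(Xs %*% solve(XtX, t_nons))
  unit_weights(frame$unit_id[s], w, method = "superpopulation",
               normalization = "N")
}

#' Doubly robust estimate of mean occupancy
#'
#' Combines the quasirandomization inclusion model and the superpopulation
#' outcome model so that the estimate is consistent if either component is
#' correctly specified:
#' \deqn{\bar{y}_{dr} = \frac{1}{N} \sum_{i \in s} \frac{r_i}{\hat{p}_i}
#'   + \frac{1}{N} \sum_{i=1}^{N} \hat{y}_i,}
#' where \eqn{r_i = y_i - \hat{y}_i} are the outcome-model residuals on the
#' sampled units. The second term is the outcome model's prediction of the
#' population mean; the first corrects it using inverse pseudo-inclusion
#' probabilities. When the outcome model is exact all residuals vanish and
#' the estimate equals the prediction term; when both components are wrong
#' the estimate may be biased.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param propensity A `propensity_fit` from
#'   [estimate_propensity_weights()].
#' @param superpop A `superpopulation_fit` from
#'   [superpopulation_estimate()].
#' @return A proportion (may fall slightly outside \[0, 1\]; reported
#'   as-is).
#' @export
doubly_robust_estimate <- function(frame, period = 1L, propensity, superpop) {
  stopifnot(inherits(propensity, "propensity_fit"),
            inherits(superpop, "superpopulation_fit"))
  N <- nrow(frame)
  if (length(propensity$p_hat) != N || length(superpop$y_hat) != N)
    stop("component fits do not match the frame's population size",
         call. = FALSE)
  s <- superpop$sampled
  p_s <- propensity$p_hat[s]
  if (any(p_s == 0))
    stop("fitted inclusion probability of 0 among sampled units; cannot divide",
         call. = FALSE)
  sum(superpop$residuals / p_s) / N + sum(superpop$y_hat) / N
}
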