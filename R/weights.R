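#' Per-sampled-unit weights
#'
#' A container for the unit weights produced by an adjustment method.
#' Weighted estimation uses the Hajek ratio form, which is invariant to
#' rescaling, so the `normalization` tag records what the weight total
#' targets (the population size `N`, the sample size `n`, or `arbitrary`)
#' without affecting the estimate.
#'
#' @param unit_ids Identifiers of the sampled units, in the order of `w`.
#' @param w Numeric weight per sampled unit. Must be strictly positive for
#'   every method except `superpopulation`, whose implied weights are
#'   regression-calibration weights and may be negative.
#' @param method Label of the producing method.
#' @param normalization What the weight total targets.
#' @return An object of class `unit_weights`.
#' @export
unit_weights <- function(unit_ids, w,
                         method = c("design", "naive", "quasirandomization",
                                    "poststratification", "superpopulation"),
                         normalization = c("arbitrary", "N", "n")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  if (length(unit_ids) != length(w))
    stop("`unit_ids` and `w` must have the same length", call. = FALSE)
  if (any(!is.finite(w)))
    stop("weights must be finite", call. = FALSE)
  if (method != "superpopulation" && any(w <= 0))
    stop(sprintf("`%s` weights must be strictly positive", method),
         call. = FALSE)
  structure(list(unit_ids = unit_ids, w = as.numeric(w),
                 method = method, normalization = normalization),
            class = "unit_weights")
}

#' @export
print.unit_weights <- function(x, ...) {
  cat(sprintf("Unit weights (%s, sum targets %s): n = %d, sum(w) = %.4f, range [%.4g, %.4g]\n",
              x$method, x$normalization, length(x$w), sum(x$w),
              min(x$w), max(x$w)))
  invisible(x)
}

#' Write weights as a two-column delimited table
#'
#' @param weights A [unit_weights()] object.
#' @param path Output CSV path.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "unit_weights"))
  utils::write.csv(data.frame(unit_id = weights$unit_ids, weight = weights$w),
                   path, row.names = FALSE)
  invisible(path)
}

#' Hajek weighted mean of sampled occupancy
#'
#' The design-based (ratio) estimator
#' \eqn{\bar{y}_w = \sum_{i \in s} y_i w_i / \sum_{i \in s} w_i}.
#' With weights equal to reciprocal inclusion probabilities this is the
#' classical design-based estimator; every weighting-based adjustment
#' method feeds its own weights through this same form.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param weights A [unit_weights()] object covering exactly the sampled
#'   units of the period (matched by `unit_id`).
#' @return The weighted mean (a proportion for 0/1 outcomes and positive
#'   weights).
#' @export
weighted_mean <- function(frame, period, weights) {
  stopifnot(inherits(weights, "unit_weights"))
  s <- sampled_index(frame, period)
  ids <- frame$unit_id[s]
  if (length(ids) != length(weights$unit_ids) ||
      !setequal(ids, weights$unit_ids))
    stop("weights must cover exactly the sampled units of this period",
         call. = FALSE)
  w <- weights$w[match(ids, weights$unit_ids)]
  total <- sum(w)
  if (total <= 0) stop("total weight must be positive", call. = FALSE)
  y <- period_column(frame, "y", period)[s]
  sum(y * w) / total
}

#' Naive (unadjusted) sample mean
#'
#' Treats every sampled unit as equally weighted (`w = 1/n`): the sample
#' mean, which ignores how unrepresentative the sample is. Widely used, and
#' the baseline every adjustment method is compared against.
#'
#' @inheritParams weighted_mean
#' @param interval Interval construction: `"normal"` for the analytic
#'   binomial-proportion interval, `"none"` for a bare point estimate.
#' @param level Confidence level.
#' @return An [estimate_result()] with method `"naive"`.
#' @export
naive_mean <- function(frame, period = 1L, interval = c("normal", "none"),
                       level = 0.95) {
  interval <- match.arg(interval)
  s <- sampled_index(frame, period)
  if (length(s) == 0L) stop("no sampled units in this period", call. = FALSE)
  y <- period_column(frame, "y", period)[s]
  point <- mean(y)
  if (interval == "normal" && length(s) >= 2L) {
    ci <- analytic_interval(frame, period, weights = NULL, level = level)
    estimate_result("naive", period, point, ci$lo, ci$hi, "normal",
                    se = ci$se)
  } else {
    estimate_result("naive", period, point, NA_real_, NA_real_, "none")
  }
}

#' A method-by-period estimate of mean occupancy
#'
#' Light container pairing a point estimate with its 95% interval and the
#' interval-construction tag; stochastic methods can carry their replicate
#' (bootstrap) or posterior draws for trend estimation.
#'
#' @param method Method label.
#' @param period Period label.
#' @param point Point estimate.
#' @param lo,hi Interval endpoints (may be `NA`).
#' @param interval_method One of `"percentile-bootstrap"`, `"normal"`,
#'   `"posterior-credible"`, `"none"`.
#' @param draws Optional replicate/posterior draws of the estimate.
#' @param se Optional standard error (normal intervals).
#' @param notes Optional character notes (e.g. convergence flags).
#' @return An object of class `estimate_result`.
#' @export
estimate_result <- function(method, period, point, lo = NA_real_,
                            hi = NA_real_,
                            interval_method = c("none", "percentile-bootstrap",
                                                "normal", "posterior-credible"),
                            draws = NULL, se = NULL, notes = character()) {
  interval_method <- match.arg(interval_method)
  structure(list(method = method, period = period, point = point,
                 lo = lo, hi = hi, interval_method = interval_method,
                 draws = draws, se = se, notes = notes),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s estimate, period %s: %.4f", x$method, x$period, x$point))
  if (!is.na(x$lo))
    cat(sprintf("  [%.4f, %.4f] (%s)", x$lo, x$hi, x$interval_method))
  cat("\n")
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(method = x$method, period = x$period, point = x$point,
             lo = x$lo, hi = x$hi, interval_method = x$interval_method,
             stringsAsFactors = FALSE)
}
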