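#' Quasirandomization: pseudo-inclusion probabilities and weights
#'
#' Imagines that the nonprobability sample was selected probabilistically
#' and estimates the implied inclusion probabilities with a binary model of
#' the inclusion indicator on covariates, fitted over the whole population
#' frame. This is prediction rather than inference — whether each unit was
#' sampled is known for the entire frame, so there are no missing data.
#' Sampled units receive weights equal to the reciprocals of their fitted
#' probabilities; feeding them through [weighted_mean()] gives the
#' quasirandomization estimate.
#'
#' @param frame A `population_frame` with realized inclusion.
#' @param period Period index.
#' @param model_kind `"logistic"` for a logistic regression (the default:
#'   transparent and fast), or `"forest"` for a probability forest via the
#'   `ranger` package (a flexible ensemble able to capture non-additive
#'   inclusion surfaces).
#' @param covariates Column names used as predictors; defaults to the two
#'   auxiliaries.
#' @param clip Lower clipping bound for fitted probabilities, guarding
#'   against unbounded weights. Probabilities are clipped to
#'   `[clip, 1]`; the number of clipped units is recorded on the fit.
#' @param num_trees Trees for the forest model.
#' @return A list with components `fit` (a `propensity_fit`: fitted
#'   probability for every population unit, model kind, covariates, clip
#'   count) and `weights` (a [unit_weights()] object for the sampled
#'   units).
#' @export
estimate_propensity_weights <- function(frame, period = 1L,
                                        model_kind = c("logistic", "forest"),
                                        covariates = c("elevation",
                                                       "protected_prop"),
                                        clip = 1e-6,
                                        num_trees = 500L) {
  model_kind <- match.arg(model_kind)
  R <- period_column(frame, "R", period)
  if (length(unique(R)) < 2L)
    stop("inclusion indicator is constant over the frame; no variation to model",
         call. = FALSE)
  missing_cov <- setdiff(covariates, names(frame))
  if (length(missing_cov))
    stop("covariates not in frame: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)

  dat <- frame[, covariates, drop = FALSE]
  dat$.R <- R
  form <- if (length(covariates)) stats::reformulate(covariates, ".R")
          else stats::as.formula(".R ~ 1")
  if (model_kind == "logistic") {
    fit <- stats::glm(form, family = stats::binomial(), data = dat)
    p_hat <- as.numeric(stats::fitted(fit))
  } else {
    if (!requireNamespace("ranger", quietly = TRUE))
      stop("the forest propensity model needs the `ranger` package",
           call. = FALSE)
    dat$.R <- factor(dat$.R, levels = c(0, 1))
    rf <- ranger::ranger(form, data = dat,
                         probability = TRUE, num.trees = num_trees,
                         respect.unordered.factors = TRUE)
    p_hat <- rf$predictions[, "1"]
  }

  n_clipped <- sum(p_hat < clip | p_hat > 1)
  if (n_clipped > 0L)
    message(sprintf("clipped %d fitted inclusion probabilities to [%g, 1]",
                    n_clipped, clip))
  p_hat <- pmin(pmax(p_hat, clip), 1)

  s <- which(R == 1L)
  w <- unit_weights(frame$unit_id[s], 1 / p_hat[s],
                    method = "quasirandomization", normalization = "N")
  fit_obj <- structure(list(model_kind = model_kind, p_hat = p_hat,
                            covariates = covariates, clip = clip,
                            n_clipped = n_clipped, period = period),
                       class = "propensity_fit")
  list(fit = fit_obj, weights = w)
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity fit (%s) on %s: p-hat in [%.4g, %.4g], %d clipped\n",
              x$model_kind, paste(x$covariates, collapse = " + "),
              min(x$p_hat), max(x$p_hat), x$n_clipped))
  invisible(x)
}

#' Quasirandomization estimate of mean occupancy
#'
#' Convenience wrapper: fits the propensity model and returns the Hajek
#' weighted mean with reciprocal-probability weights.
#'
#' @inheritParams estimate_propensity_weights
#' @return A proportion.
#' @export
quasirandomization_estimate <- function(frame, period = 1L,
                                        model_kind = c("logistic", "forest"),
                                        covariates = c("elevation",
                                                       "protected_prop"),
                                        clip = 1e-6) {
  pw <- estimate_propensity_weights(frame, period, model_kind = model_kind,
                                    covariates = covariates, clip = clip)
  weighted_mean(frame, period, pw$weights)
}
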