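#' Configuration for a synthetic landscape
#'
#' Defines the generative model for a finite population of areal units
#' (think 1-km grid squares) whose occupancy and sample-inclusion mechanisms
#' have the structure that nonprobability-sample adjustment methods assume:
#' two continuous auxiliary variables (elevation and the proportion of the
#' unit under protected-area designation) drive both whether a unit is
#' occupied and whether it ends up in the sample.
#'
#' Occupancy and inclusion are Bernoulli with logistic links on the
#' standardized (z-scored) auxiliaries, so coefficient magnitudes are
#' comparable across configurations. `gamma_y` adds a direct effect of
#' occupancy itself on the inclusion log-odds; with `gamma_y = 0` the
#' outcome is independent of inclusion given the auxiliaries (the
#' missing-at-random assumption holds by construction), while nonzero
#' values violate it in a controlled way.
#'
#' The defaults emulate a national plant-atlas setting: a right-skewed
#' elevation distribution, protected-area coverage that is zero for most
#' units, recorders who under-visit high ground and favour protected land,
#' and occupancy (of an upland shrub) that increases with both auxiliaries.
#' Period one has a sampling fraction near 0.43 with data defect correlation
#' around -0.12; period two samples more widely (fraction near 0.62, ddc
#' around -0.06) while true mean occupancy declines by about 0.05.
#'
#' @param N Population size (number of areal units), at least 2.
#' @param occupancy_coefs Coefficients (intercept, elevation slope,
#'   protected slope) of the logistic occupancy model, either a single
#'   numeric vector of length 3 used for every period or a list with one
#'   such vector per period.
#' @param inclusion_coefs Same shape as `occupancy_coefs`, for the logistic
#'   sample-inclusion model.
#' @param gamma_y Direct effect of occupancy on the inclusion log-odds;
#'   scalar or one value per period. Zero means inclusion is ignorable
#'   given the auxiliaries.
#' @param zero_inflation Probability that a unit has no protected-area
#'   coverage at all (`protected_prop = 0`).
#' @param n_periods Number of time periods.
#' @param seed Integer random seed recorded in the frame's metadata.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_population()], [apply_inclusion_mechanism()],
#'   [simulate_landscape()]
#' @examples
#' cfg <- synthetic_config(N = 1000, seed = 1)
#' frame <- simulate_landscape(cfg)
#' population_mean(frame, period = 1)
#' @export
synthetic_config <- function(N = 10000,
                             occupancy_coefs = list(c(-0.886, 1.2, 0.5),
                                                    c(-1.209, 1.2, 0.5)),
                             inclusion_coefs = list(c(-0.429, -1.15, 0.6),
                                                    c(0.519, -0.42, 0.35)),
                             gamma_y = 0,
                             zero_inflation = 0.6,
                             n_periods = 2,
                             seed = 1L) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 2)
    stop("`N` must be a single finite number >= 2", call. = FALSE)
  N <- as.integer(N)
  n_periods <- as.integer(n_periods)
  if (n_periods < 1L) stop("`n_periods` must be >= 1", call. = FALSE)

  occupancy_coefs <- rep_coefs(occupancy_coefs, n_periods, "occupancy_coefs")
  inclusion_coefs <- rep_coefs(inclusion_coefs, n_periods, "inclusion_coefs")
  gamma_y <- rep_len(as.numeric(gamma_y), n_periods)
  if (any(!is.finite(gamma_y)))
    stop("`gamma_y` must be finite", call. = FALSE)
  if (!is.numeric(zero_inflation) || zero_inflation < 0 || zero_inflation > 1)
    stop("`zero_inflation` must lie in [0, 1]", call. = FALSE)

  structure(
    list(N = N,
         occupancy_coefs = occupancy_coefs,
         inclusion_coefs = inclusion_coefs,
         gamma_y = gamma_y,
         zero_inflation = zero_inflation,
         n_periods = n_periods,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# recycle a single coefficient vector to one per period, validating finiteness
rep_coefs <- function(coefs, n_periods, what) {
  if (is.numeric(coefs)) coefs <- rep(list(coefs), n_periods)
  if (is.list(coefs) && length(coefs) > n_periods)
    coefs <- coefs[seq_len(n_periods)]
  if (is.list(coefs) && length(coefs) == 1L && n_periods > 1L)
    coefs <- rep(coefs, n_periods)
  if (!is.list(coefs) || length(coefs) != n_periods)
    stop(sprintf("`%s` must be one numeric vector or a list of %d", what,
                 n_periods), call. = FALSE)
  for (b in coefs) {
    if (!is.numeric(b) || length(b) != 3L || any(!is.finite(b)))
      stop(sprintf("each `%s` vector must be 3 finite numbers (intercept, elevation, protected)",
                   what), call. = FALSE)
  }
  coefs
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic landscape config: N = %d, %d period(s), seed = %d\n",
              x$N, x$n_periods, x$seed))
  for (p in seq_len(x$n_periods)) {
    cat(sprintf("  period %d: occupancy (%s)  inclusion (%s)  gamma_y = %g\n",
                p, paste(format(x$occupancy_coefs[[p]]), collapse = ", "),
                paste(format(x$inclusion_coefs[[p]]), collapse = ", "),
                x$gamma_y[p]))
  }
  invisible(x)
}

#' Generate a finite population of areal units
#'
#' Draws the auxiliaries and the true occupancy surface for every unit,
#' and computes (but does not yet realize) each unit's true inclusion
#' probability. Elevation is drawn from a right-skewed gamma distribution
#' (shape 1.5, scale 90, in metres); protected-area proportion is
#' zero-inflated uniform on \[0, 1\]. Occupancy per period is Bernoulli with
#' logit equal to the occupancy coefficients dotted with the standardized
#' auxiliaries. Use [apply_inclusion_mechanism()] to realize the sample
#' inclusion indicators.
#'
#' @param config A [synthetic_config()] object.
#' @return A `population_frame`: a data frame with one row per unit and
#'   columns `unit_id`, `elevation`, `protected_prop`, and per period `p`
#'   the columns `y_p<p>` (binary occupancy) and `p_true_p<p>` (true
#'   inclusion probability). Attributes record the number of periods and
#'   the seed.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  N <- config$N

  elevation <- stats::rgamma(N, shape = 1.5, scale = 90)
  at_zero <- stats::runif(N) < config$zero_inflation
  protected_prop <- ifelse(at_zero, 0, stats::runif(N))

  z_elev <- as.numeric(scale(elevation))
  z_prot <- as.numeric(scale(protected_prop))
  # scale() returns NaN when a column is constant; treat as centred zeros
  if (anyNA(z_elev)) z_elev <- rep(0, N)
  if (anyNA(z_prot)) z_prot <- rep(0, N)

  frame <- data.frame(unit_id = sprintf("u%06d", seq_len(N)),
                      elevation = elevation,
                      protected_prop = protected_prop,
                      stringsAsFactors = FALSE)

  for (p in seq_len(config$n_periods)) {
    b <- config$occupancy_coefs[[p]]
    pr_y <- stats::plogis(b[1] + b[2] * z_elev + b[3] * z_prot)
    frame[[paste0("y_p", p)]] <- stats::rbinom(N, 1L, pr_y)
    g <- config$inclusion_coefs[[p]]
    frame[[paste0("p_true_p", p)]] <-
      stats::plogis(g[1] + g[2] * z_elev + g[3] * z_prot +
                      config$gamma_y[p] * frame[[paste0("y_p", p)]])
  }

  structure(frame,
            class = c("population_frame", "data.frame"),
            n_periods = config$n_periods,
            seed = config$seed,
            synthetic = TRUE)
}

#' Realize sample inclusion for every period
#'
#' Draws each unit's sample-inclusion indicator independently as
#' Bernoulli(p_true) — Poisson sampling, with no fixed sample size, which
#' matches how opportunistic recording actually accrues. A realization in
#' which every unit, or no unit, is sampled is degenerate for estimation;
#' such draws are retried up to `max_retries` times (with a message) and an
#' error is thrown if the design is so extreme that no usable realization
#' appears.
#'
#' @param frame A `population_frame` from [generate_population()].
#' @param config The same [synthetic_config()] used to build `frame`
#'   (supplies `inclusion_coefs` and `gamma_y` provenance; the realized
#'   probabilities are read from the frame's `p_true_p*` columns).
#' @param max_retries Bounded retry count for degenerate realizations.
#' @return The frame with added binary columns `R_p<p>`.
#' @export
apply_inclusion_mechanism <- function(frame, config, max_retries = 100L) {
  stopifnot(inherits(frame, "population_frame"))
  n_periods <- attr(frame, "n_periods")
  N <- nrow(frame)
  for (p in seq_len(n_periods)) {
    p_true <- frame[[paste0("p_true_p", p)]]
    if (is.null(p_true))
      stop("frame has no true inclusion probabilities; run generate_population() first",
           call. = FALSE)
    R <- stats::rbinom(N, 1L, p_true)
    tries <- 0L
    while ((sum(R) == 0L || sum(R) == N) && tries < max_retries) {
      tries <- tries + 1L
      R <- stats::rbinom(N, 1L, p_true)
    }
    if (sum(R) == 0L || sum(R) == N)
      stop(sprintf("degenerate inclusion design in period %d: all or no units sampled after %d retries",
                   p, max_retries), call. = FALSE)
    if (tries > 0L)
      message(sprintf("period %d: resampled inclusion %d time(s) to avoid a degenerate realization",
                      p, tries))
    frame[[paste0("R_p", p)]] <- R
  }
  frame
}

#' Generate a population and realize its samples in one call
#'
#' @inheritParams generate_population
#' @param max_retries Passed to [apply_inclusion_mechanism()].
#' @return A complete `population_frame` with occupancy, auxiliaries,
#'   inclusion indicators and true inclusion probabilities.
#' @export
simulate_landscape <- function(config, max_retries = 100L) {
  apply_inclusion_mechanism(generate_population(config), config,
                            max_retries = max_retries)
}

#' True population mean occupancy
#'
#' The proportion of all areal units occupied in a period — the target of
#' descriptive inference. Equal, exactly, to the weighted form
#' \eqn{\sum_i y_i w_i / \sum_i w_i} with constant weights \eqn{w_i = 1/N}.
#'
#' @param frame A `population_frame` (or any data frame with a `y_p<p>`
#'   column).
#' @param period Period index.
#' @return A proportion in \[0, 1\].
#' @export
population_mean <- function(frame, period = 1L) {
  y <- period_column(frame, "y", period)
  if (length(y) == 0L) stop("empty frame", call. = FALSE)
  mean(y)
}

# pull a per-period column (y, R, p_true), failing with a clear message
period_column <- function(frame, prefix, period) {
  col <- paste0(prefix, "_p", period)
  v <- frame[[col]]
  if (is.null(v))
    stop(sprintf("frame has no column `%s`", col), call. = FALSE)
  v
}

# indices of sampled units in a period
sampled_index <- function(frame, period) {
  which(period_column(frame, "R", period) == 1L)
}
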