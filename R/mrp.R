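# JAGS model: binomial cell counts, logit link, fixed intercept, random
# intercepts for each discretized auxiliary and their interaction.
# Priors: weakly-informative normal on the intercept, half-normal(1) on the
# random-intercept scales.
mrp_model_string <- "
model {
  for (c in 1:C) {
    k[c] ~ dbin(theta[obs_cell[c]], n[c])
  }
  for (j in 1:J) {
    logit(theta[j]) <- mu + a[elev[j]] + b[prot[j]] + ab[j]
    ab[j] ~ dnorm(0, tau_ab)
  }
  for (e in 1:E) { a[e] ~ dnorm(0, tau_a) }
  for (p in 1:P) { b[p] ~ dnorm(0, tau_b) }
  mu ~ dnorm(0, 0.25)
  sigma_a ~ dnorm(0, 1) T(0,)
  sigma_b ~ dnorm(0, 1) T(0,)
  sigma_ab ~ dnorm(0, 1) T(0,)
  tau_a <- pow(sigma_a, -2)
  tau_b <- pow(sigma_b, -2)
  tau_ab <- pow(sigma_ab, -2)
}"

#' Multilevel regression and poststratification (MRP)
#'
#' Fits a hierarchical binomial model of per-poststratum occupancy — a
#' binomial GLM with a logit link, a fixed intercept, and random intercepts
#' for the two discretized auxiliaries and their interaction — by MCMC, and
#' poststratifies: for each posterior draw the population mean is the
#' population-share-weighted average of the cell probabilities,
#' \eqn{\sum_j (N_j/N)\,\theta_j}. Partial pooling lets cells with few or
#' no sampled units borrow strength from the rest, so empty cells still get
#' finite, shrunken estimates.
#'
#' Convergence is checked with the split-\eqn{\hat{R}} statistic on the
#' identified quantities — the poststratified mean and every cell
#' probability \eqn{\theta_j}; values above 1.05 flag the result (a note is
#' attached and a warning raised) rather than failing silently. The fixed
#' intercept and the random-intercept means are additively aliased (only
#' their sums enter the likelihood), so their chains wander jointly by
#' construction; the cell probabilities and the estimand are unaffected.
#'
#' @param frame A `population_frame` with realized inclusion.
#' @param period Period index.
#' @param strata A [build_poststrata()] result; defaults to the standard
#'   10 x 2 poststrata. Empty-cell collapsing is unnecessary here (the
#'   model pools instead), so strata built with `collapse_empty = FALSE`
#'   are fine.
#' @param chains Number of MCMC chains.
#' @param iterations Posterior iterations kept per chain (after `burnin`
#'   warm-up updates).
#' @param burnin Adaptation/burn-in updates per chain.
#' @param level Credible level.
#' @param seed Integer seed; chain RNGs are seeded deterministically from
#'   it.
#' @return An [estimate_result()] with method `"mrp"`, the posterior mean
#'   as point estimate, a central credible interval, the posterior draws of
#'   the population mean, and additional elements `cell_means` (posterior
#'   mean occupancy per stratum) and `rhat` (split-R-hat diagnostics).
#' @export
mrp_estimate <- function(frame, period = 1L, strata = NULL, chains = 5L,
                         iterations = 1000L, burnin = 500L, level = 0.95,
                         seed = NULL) {
  if (is.null(strata))
    strata <- build_poststrata(frame, period, collapse_empty = FALSE)
  tab <- strata$table
  R <- period_column(frame, "R", period)
  y <- period_column(frame, "y", period)
  s <- which(R == 1L)
  cell_of_sampled <- strata$assignment[s]
  k <- as.integer(tapply(y[s], factor(cell_of_sampled,
                                      levels = tab$stratum), sum,
                         default = 0L))
  nj <- tab$nj

  elev_levels <- sort(unique(tab$elev_bin))
  prot_levels <- sort(unique(tab$protected))
  observed <- which(nj > 0L)
  data <- list(C = length(observed),
               k = k[observed], n = nj[observed], obs_cell = observed,
               J = nrow(tab),
               elev = match(tab$elev_bin, elev_levels),
               prot = match(tab$protected, prot_levels),
               E = length(elev_levels), P = length(prot_levels))

  inits <- NULL
  if (!is.null(seed)) {
    inits <- lapply(seq_len(chains), function(ch)
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = as.integer(seed) + ch))
  }
  jm <- rjags::jags.model(textConnection(mrp_model_string), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = burnin, quiet = TRUE)
  stats::update(jm, burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "theta", n.iter = iterations,
                              progress.bar = "none")

  share <- tab$Nj / strata$N
  theta_cols <- paste0("theta[", seq_len(nrow(tab)), "]")
  ybar_chains <- lapply(samp, function(m) {
    as.numeric(as.matrix(m)[, theta_cols, drop = FALSE] %*% share)
  })
  ybar <- unlist(ybar_chains, use.names = FALSE)

  theta_rhat <- vapply(theta_cols, function(cl)
    split_rhat(lapply(samp, function(m) as.matrix(m)[, cl])), numeric(1))
  rhat <- c(ybar = split_rhat(ybar_chains), theta_rhat)
  notes <- character()
  if (any(rhat > 1.05, na.rm = TRUE)) {
    notes <- sprintf("possible non-convergence: max split-Rhat = %.3f",
                     max(rhat, na.rm = TRUE))
    warning(notes)
  }

  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(ybar, c(alpha, 1 - alpha)))
  res <- estimate_result("mrp", period, mean(ybar), ci[1], ci[2],
                         "posterior-credible", draws = ybar, notes = notes)
  theta_mat <- do.call(rbind, lapply(samp, function(m)
    as.matrix(m)[, theta_cols, drop = FALSE]))
  res$cell_means <- colMeans(theta_mat)
  res$rhat <- rhat
  res
}

# split-Rhat: halve each chain, then the usual between/within ratio
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    m <- length(x) %/% 2L
    list(x[seq_len(m)], x[(m + 1L):(2L * m)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
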