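# Hand-built single-period population frames for exact oracle tests.
make_frame <- function(y, R = NULL, elevation = NULL, protected = NULL,
                       p_true = NULL) {
  N <- length(y)
  fr <- data.frame(
    unit_id = sprintf("u%04d", seq_len(N)),
    elevation = if (is.null(elevation)) seq_len(N) else elevation,
    protected_prop = if (is.null(protected)) rep(0, N) else protected,
    y_p1 = y,
    stringsAsFactors = FALSE)
  if (!is.null(R)) fr$R_p1 <- R
  if (!is.null(p_true)) fr$p_true_p1 <- p_true
  structure(fr, class = c("population_frame", "data.frame"),
            n_periods = 1L, synthetic = !is.null(p_true))
}

# A frame with two poststrata of chosen counts/means: stratum 1 has low
# elevation, stratum 2 high, all protected_prop = 0.
make_two_stratum_frame <- function(N1, n1, ybar1, N2, n2, ybar2) {
  y1 <- c(rep(1, round(N1 * ybar1)), rep(0, N1 - round(N1 * ybar1)))
  y2 <- c(rep(1, round(N2 * ybar2)), rep(0, N2 - round(N2 * ybar2)))
  # sample the first n of each stratum after interleaving 1s and 0s so the
  # sample mean of each stratum equals its target
  pick <- function(y, n) {
    ones <- which(y == 1); zeros <- which(y == 0)
    k <- round(n * mean(y))
    c(ones[seq_len(k)], zeros[seq_len(n - k)])
  }
  R1 <- integer(N1); R1[pick(y1, n1)] <- 1L
  R2 <- integer(N2); R2[pick(y2, n2)] <- 1L
  make_frame(y = c(y1, y2), R = c(R1, R2),
             elevation = c(stats::runif(N1, 0, 10),
                           stats::runif(N2, 20, 30)))
}

# quick default synthetic frame for property tests
default_frame <- function(N = 3000, seed = 42, gamma_y = 0) {
  simulate_landscape(synthetic_config(N = N, seed = seed,
                                      gamma_y = gamma_y))
}
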