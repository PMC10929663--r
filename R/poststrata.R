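#' Build poststrata by crossing discretized auxiliaries
#'
#' Elevation is cut into categories at its population deciles (cut points
#' at the 10th, 20th, ... percentiles; left-open/right-closed intervals,
#' lowest included) and protected-area proportion is dichotomized at 0
#' versus >0, since most units have either no protected coverage or a lot.
#' Crossing the two gives (by default) 10 x 2 = 20 poststrata, each with a
#' population count `Nj` and a sample count `nj`.
#'
#' Tied decile cut points are collapsed (fewer elevation categories, with a
#' message). A stratum that exists in the population but has no sampled
#' units would make the weight `Nj/nj` undefined; by default such a cell is
#' merged with the nearest nonempty elevation bin in the same protected
#' class (`collapse_empty = TRUE`), otherwise it is flagged and
#' [poststratification_weights()] will refuse to proceed.
#'
#' @param frame A `population_frame` with realized inclusion.
#' @param period Period index.
#' @param elevation_bins Number of elevation categories (quantile cuts).
#' @param collapse_empty Merge population strata that caught no sampled
#'   units into their nearest elevation neighbour?
#' @return A `stratum_table`: the per-stratum counts plus each unit's
#'   stratum assignment.
#' @export
build_poststrata <- function(frame, period = 1L, elevation_bins = 10L,
                             collapse_empty = TRUE) {
  elevation <- frame$elevation
  protected <- frame$protected_prop
  if (is.null(elevation) || is.null(protected))
    stop("frame must have `elevation` and `protected_prop` columns",
         call. = FALSE)
  if (length(unique(elevation)) < elevation_bins)
    stop("elevation has fewer distinct values than requested bins",
         call. = FALSE)
  R <- period_column(frame, "R", period)

  cuts <- stats::quantile(elevation, probs = seq(0, 1,
                                                 length.out = elevation_bins + 1L),
                          names = FALSE)
  cuts_u <- unique(cuts)
  if (length(cuts_u) < length(cuts))
    message(sprintf("tied decile cut points: %d elevation bins collapsed to %d",
                    elevation_bins, length(cuts_u) - 1L))
  elev_bin <- as.integer(cut(elevation, breaks = cuts_u,
                             include.lowest = TRUE, right = TRUE))
  prot_bin <- ifelse(protected > 0, 2L, 1L)
  n_elev <- length(cuts_u) - 1L

  # merge empty-but-populated cells into the nearest sampled elevation bin
  # within the same protected class
  if (collapse_empty) {
    repeat {
      key <- paste(elev_bin, prot_bin, sep = ":")
      nj <- tapply(R, key, sum)
      bad <- names(nj)[nj == 0L]
      if (!length(bad)) break
      cell <- strsplit(bad[1L], ":", fixed = TRUE)[[1L]]
      e <- as.integer(cell[1L]); pr <- as.integer(cell[2L])
      sampled_bins <- sort(unique(elev_bin[prot_bin == pr & R == 1L]))
      if (!length(sampled_bins))
        stop("no sampled units in an entire protected class; cannot collapse",
             call. = FALSE)
      target <- sampled_bins[which.min(abs(sampled_bins - e))]
      message(sprintf("collapsing empty poststratum (elevation bin %d, protected class %d) into elevation bin %d",
                      e, pr, target))
      elev_bin[elev_bin == e & prot_bin == pr] <- target
    }
  }

  key <- paste(elev_bin, prot_bin, sep = ":")
  levs <- sort(unique(key))
  stratum <- match(key, levs)
  Nj <- tabulate(stratum, nbins = length(levs))
  nj <- as.integer(tapply(R, factor(stratum, levels = seq_along(levs)), sum,
                          default = 0L))
  parts <- do.call(rbind, strsplit(levs, ":", fixed = TRUE))
  table <- data.frame(stratum = seq_along(levs),
                      elev_bin = as.integer(parts[, 1L]),
                      protected = c("0", ">0")[as.integer(parts[, 2L])],
                      Nj = Nj, nj = nj, stringsAsFactors = FALSE)
  table$weight <- ifelse(table$nj > 0, table$Nj / table$nj, NA_real_)

  structure(list(table = table,
                 assignment = stratum,
                 unit_id = frame$unit_id,
                 period = period,
                 N = nrow(frame), n = sum(R),
                 n_elevation_bins = n_elev,
                 elevation_cuts = cuts_u),
            class = "stratum_table")
}

#' @export
print.stratum_table <- function(x, ...) {
  cat(sprintf("Poststrata (period %s): %d strata, N = %d, n = %d\n",
              x$period, nrow(x$table), x$N, x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Poststratification weights Nj/nj
#'
#' Every sampled unit in stratum `j` receives weight `Nj/nj`, so the
#' weighted sample reproduces each stratum's population count exactly and
#' the weight total equals the population size `N`. Feeding these weights
#' through [weighted_mean()] gives the poststratified estimate.
#'
#' @param strata A [build_poststrata()] result.
#' @param frame The frame the strata were built from (supplies the
#'   inclusion indicator; must be row-aligned with the strata).
#' @return A [unit_weights()] object.
#' @export
poststratification_weights <- function(strata, frame) {
  stopifnot(inherits(strata, "stratum_table"))
  tab <- strata$table
  bad <- tab$Nj > 0 & tab$nj == 0
  if (any(bad))
    stop("poststrata with population units but no sampled units remain; rebuild with collapse_empty = TRUE",
         call. = FALSE)
  R <- period_column(frame, "R", strata$period)
  s <- which(R == 1L)
  w <- tab$weight[strata$assignment[s]]
  unit_weights(frame$unit_id[s], w, method = "poststratification",
               normalization = "N")
}

#' Poststratified estimate of mean occupancy
#'
#' @inheritParams build_poststrata
#' @param strata Optional prebuilt [build_poststrata()] result.
#' @return A proportion.
#' @export
poststratification_estimate <- function(frame, period = 1L, strata = NULL,
                                        elevation_bins = 10L) {
  if (is.null(strata))
    strata <- build_poststrata(frame, period, elevation_bins = elevation_bins)
  weighted_mean(frame, period, poststratification_weights(strata, frame))
}

#' Stratified subsample estimate of mean occupancy
#'
#' Builds a representative "miniature" of the population from the sample:
#' sampled units are drawn with replacement, stratum by stratum, in
#' proportion to each stratum's population share `Nj/N`, and the subsample
#' mean is the estimate. Subsampling trades sample size for
#' representativeness. The default subsample size is `N/10`, a choice that
#' has little effect on the point estimate (larger subsamples are merely
#' more precise).
#'
#' Per-stratum allocations use largest-remainder rounding so the total
#' equals the requested size exactly.
#'
#' @param frame A `population_frame`.
#' @param period Period index.
#' @param strata A [build_poststrata()] result (defaults to the standard
#'   10 x 2 poststrata).
#' @param size Total subsample size; defaults to `round(N / 10)`.
#' @param seed Optional seed for reproducibility.
#' @param n_replicates Number of independent subsamples to draw.
#' @return A numeric vector of `n_replicates` subsample means (a single
#'   proportion by default), with the per-stratum allocation attached as
#'   attribute `"allocation"`.
#' @export
stratified_subsample_mean <- function(frame, period = 1L, strata = NULL,
                                      size = NULL, seed = NULL,
                                      n_replicates = 1L) {
  if (is.null(strata)) strata <- build_poststrata(frame, period)
  if (is.null(size)) size <- round(nrow(frame) / 10)
  if (!is.null(seed)) set.seed(seed)
  tab <- strata$table
  if (any(tab$Nj > 0 & tab$nj == 0))
    stop("a stratum with positive allocation has no sampled units; rebuild strata with collapse_empty = TRUE",
         call. = FALSE)

  # largest-remainder apportionment of `size` across strata by Nj/N
  raw <- size * tab$Nj / strata$N
  alloc <- floor(raw)
  short <- size - sum(alloc)
  if (short > 0) {
    extra <- order(raw - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1L
  }

  R <- period_column(frame, "R", period)
  y <- period_column(frame, "y", period)
  by_stratum <- split(which(R == 1L), strata$assignment[R == 1L])

  means <- vapply(seq_len(n_replicates), function(r) {
    picks <- unlist(lapply(seq_len(nrow(tab)), function(j) {
      if (alloc[j] == 0L) return(integer())
      pool <- by_stratum[[as.character(tab$stratum[j])]]
      pool[sample.int(length(pool), alloc[j], replace = TRUE)]
    }), use.names = FALSE)
    mean(y[picks])
  }, numeric(1))
  attr(means, "allocation") <- alloc
  means
}
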