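#' Read a population frame from a delimited table
#'
#' Consumes a flat CSV with one row per areal unit carrying both periods in
#' suffix-named columns. The default layout is the one
#' [write_population_table()] produces (`unit_id`, `elevation`,
#' `protected_prop`, `y_p1`, `R_p1`, ... and optionally `p_true_p*`); any
#' other layout can be mapped by `schema`, a named list from canonical
#' names to the file's column names. Occupancy and inclusion columns must
#' be strictly 0/1; rows with missing auxiliaries are dropped with a
#' message.
#'
#' @param path CSV path.
#' @param schema Optional named list mapping canonical column names
#'   (`unit_id`, `elevation`, `protected_prop`, `y_p1`, `R_p1`, ...) to the
#'   file's column names.
#' @return A `population_frame`.
#' @export
read_population_table <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty population table: ", path, call. = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw))
        stop("schema column `", src, "` not found in ", path, call. = FALSE)
      names(raw)[names(raw) == src] <- canonical
    }
  }
  required <- c("unit_id", "elevation", "protected_prop")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y_cols <- grep("^y_p[0-9]+$", names(raw), value = TRUE)
  r_cols <- grep("^R_p[0-9]+$", names(raw), value = TRUE)
  if (!length(y_cols) || !length(r_cols))
    stop("table needs at least one `y_p<period>` and one `R_p<period>` column",
         call. = FALSE)
  for (col in c(y_cols, r_cols)) {
    v <- raw[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop("column `", col, "` must contain only 0/1 values", call. = FALSE)
  }
  incomplete <- !stats::complete.cases(raw[, required, drop = FALSE])
  if (any(incomplete)) {
    message(sprintf("dropping %d row(s) with missing auxiliaries",
                    sum(incomplete)))
    raw <- raw[!incomplete, , drop = FALSE]
  }
  if (any(raw$protected_prop < 0 | raw$protected_prop > 1))
    stop("`protected_prop` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(raw$elevation)))
    stop("`elevation` must be finite", call. = FALSE)
  raw$unit_id <- as.character(raw$unit_id)
  n_periods <- max(as.integer(sub("^y_p", "", y_cols)))
  structure(raw, class = c("population_frame", "data.frame"),
            n_periods = n_periods,
            synthetic = any(grepl("^p_true_p", names(raw))))
}

#' Write a population frame as a delimited table
#'
#' @param frame A `population_frame`.
#' @param path Output CSV path.
#' @export
write_population_table <- function(frame, path) {
  utils::write.csv(as.data.frame(frame), path, row.names = FALSE)
  invisible(path)
}

#' Configuration for an end-to-end analysis run
#'
#' @param frame A `population_frame`, or `NULL` if `input` or `synthetic`
#'   is given.
#' @param input Path to a population CSV (read with
#'   [read_population_table()]).
#' @param synthetic A [synthetic_config()] to simulate a frame from.
#' @param periods Periods to analyze.
#' @param methods Estimators to run; any subset of `"naive"`,
#'   `"quasirandomization"`, `"poststratification"`, `"superpopulation"`,
#'   `"doubly_robust"`, `"subsampling"`, `"mrp"`.
#' @param covariates Auxiliary column names for the model-based methods.
#' @param elevation_bins Elevation categories for poststratification.
#' @param B Bootstrap replicates for the bootstrap-interval methods.
#' @param chains,iterations MCMC settings for MRP.
#' @param subsample_size Stratified-subsample size (default `N/10`).
#' @param seed Integer seed recorded in the run manifest.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(frame = NULL, input = NULL, synthetic = NULL,
                            periods = NULL,
                            methods = c("naive", "quasirandomization",
                                        "poststratification",
                                        "superpopulation", "doubly_robust",
                                        "subsampling", "mrp"),
                            covariates = c("elevation", "protected_prop"),
                            elevation_bins = 10L, B = 1000L, chains = 5L,
                            iterations = 1000L, subsample_size = NULL,
                            seed = 1L) {
  known <- c("naive", "quasirandomization", "poststratification",
             "superpopulation", "doubly_robust", "subsampling", "mrp")
  unknown <- setdiff(methods, known)
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(frame) && is.null(input) && is.null(synthetic))
    stop("supply one of `frame`, `input`, or `synthetic`", call. = FALSE)
  structure(list(frame = frame, input = input, synthetic = synthetic,
                 periods = periods, methods = methods,
                 covariates = covariates,
                 elevation_bins = as.integer(elevation_bins),
                 B = as.integer(B), chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 subsample_size = subsample_size, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full descriptive-inference pipeline
#'
#' For each requested period: the naive and requested adjusted estimates of
#' mean occupancy with 95% intervals (analytic for naive and
#' poststratification, percentile bootstrap for quasirandomization,
#' superpopulation, doubly robust and subsampling, posterior credible for
#' MRP); the ddc, partial ddc and error decomposition; binned
#' auxiliary-distribution comparisons for every weight-producing method
#' plus subsampling; and, when two or more periods are present, the
#' between-period trend per method. A method that fails is recorded and the
#' run continues.
#'
#' @param config An [analysis_config()].
#' @return A `results_bundle` list with elements `estimates` (data frame),
#'   `trends` (data frame), `diagnostics` (data frame), `binned` (data
#'   frame, one row per bin), `weights` (named list of [unit_weights()]),
#'   `results` (nested list of `estimate_result`s), `errors` (named list of
#'   failure messages), and `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  frame <- config$frame
  if (is.null(frame) && !is.null(config$input))
    frame <- read_population_table(config$input)
  if (is.null(frame) && !is.null(config$synthetic))
    frame <- simulate_landscape(config$synthetic)
  periods <- config$periods
  if (is.null(periods)) periods <- seq_len(attr(frame, "n_periods"))

  results <- list()
  weights_out <- list()
  errors <- list()
  diag_rows <- list()
  binned_rows <- list()

  for (p in periods) {
    pkey <- paste0("p", p)
    results[[pkey]] <- list()
    diag_rows[[pkey]] <- as.data.frame(meng_error_decomposition(frame, p))

    for (m in config$methods) {
      res <- tryCatch(
        run_one_method(frame, p, m, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(m, pkey, sep = ".")]] <- conditionMessage(res)
        next
      }
      results[[pkey]][[m]] <- res$result
      if (!is.null(res$weights)) {
        weights_out[[paste(m, pkey, sep = ".")]] <- res$weights
        for (aux in config$covariates) {
          bc <- binned_relative_frequency_comparison(frame, p, aux,
                                                     weights = res$weights)
          binned_rows[[paste(m, pkey, aux, sep = ".")]] <-
            cbind(method = m, as.data.frame(bc))
        }
      }
      if (!is.null(res$subsample_idx)) {
        for (aux in config$covariates) {
          bc <- binned_relative_frequency_comparison(
            frame, p, aux, subsample = res$subsample_idx)
          binned_rows[[paste(m, pkey, aux, sep = ".")]] <-
            cbind(method = m, as.data.frame(bc))
        }
      }
    }
  }

  trends <- list()
  if (length(periods) >= 2L) {
    p1 <- paste0("p", periods[1L]); p2 <- paste0("p", periods[2L])
    for (m in config$methods) {
      r1 <- results[[p1]][[m]]; r2 <- results[[p2]][[m]]
      if (is.null(r1) || is.null(r2)) next
      mode <- if (!is.null(r1$draws) && !is.null(r2$draws)) "percentile"
              else "normal"
      tr <- tryCatch(trend_with_interval(r1, r2, mode = mode),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        errors[[paste(m, "trend", sep = ".")]] <- conditionMessage(tr)
      } else trends[[m]] <- tr
    }
  }

  estimates_df <- do.call(rbind, unlist(lapply(results, function(per)
    lapply(per, as.data.frame)), recursive = FALSE))
  rownames(estimates_df) <- NULL
  trends_df <- if (length(trends)) {
    do.call(rbind, lapply(trends, function(tr)
      data.frame(method = tr$method, point = tr$point, lo = tr$lo,
                 hi = tr$hi, interval_method = tr$interval_method,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(method = character(), point = numeric(), lo = numeric(),
               hi = numeric(), interval_method = character())
  }
  rownames(trends_df) <- NULL

  manifest <- list(
    seed = config$seed,
    methods = config$methods,
    periods = periods,
    covariates = config$covariates,
    elevation_bins = config$elevation_bins,
    B = config$B,
    chains = config$chains,
    iterations = config$iterations,
    N = nrow(frame),
    package_version = as.character(utils::packageVersion("occuadjust")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(estimates = estimates_df,
                 trends = trends_df,
                 diagnostics = do.call(rbind, diag_rows),
                 binned = if (length(binned_rows))
                   do.call(rbind, binned_rows) else NULL,
                 weights = weights_out,
                 results = results,
                 errors = errors,
                 manifest = manifest,
                 frame = frame),
            class = "results_bundle")
}

# one method x period: point estimate, interval, and (where defined) weights
run_one_method <- function(frame, period, method, config) {
  covs <- config$covariates
  switch(method,
    naive = list(result = naive_mean(frame, period)),
    poststratification = {
      strata <- build_poststrata(frame, period,
                                 elevation_bins = config$elevation_bins)
      w <- poststratification_weights(strata, frame)
      ci <- analytic_interval(frame, period, weights = w)
      res <- estimate_result("poststratification", period, ci$point,
                             ci$lo, ci$hi, "normal", se = ci$se)
      list(result = res, weights = w)
    },
    quasirandomization = {
      pw <- estimate_propensity_weights(frame, period, covariates = covs)
      res <- bootstrap_percentile_interval(frame, period,
                                           "quasirandomization",
                                           B = config$B, covariates = covs)
      list(result = res, weights = pw$weights)
    },
    superpopulation = {
      sp <- superpopulation_estimate(frame, period, predictors = covs)
      w <- superpopulation_implied_weights(sp$fit, frame)
      res <- bootstrap_percentile_interval(frame, period, "superpopulation",
                                           B = config$B, covariates = covs)
      list(result = res, weights = w)
    },
    doubly_robust = {
      res <- bootstrap_percentile_interval(frame, period, "doubly_robust",
                                           B = config$B, covariates = covs)
      list(result = res)
    },
    subsampling = {
      strata <- build_poststrata(frame, period,
                                 elevation_bins = config$elevation_bins)
      res <- bootstrap_percentile_interval(frame, period, "subsampling",
                                           B = config$B,
                                           elevation_bins = config$elevation_bins,
                                           subsample_size = config$subsample_size)
      sub_idx <- draw_subsample_indices(frame, period, strata,
                                        config$subsample_size)
      list(result = res, subsample_idx = sub_idx)
    },
    mrp = {
      res <- mrp_estimate(frame, period, chains = config$chains,
                          iterations = config$iterations,
                          seed = config$seed + period)
      list(result = res)
    },
    stop("unknown method: ", method, call. = FALSE))
}

# indices (with repeats) of one stratified subsample, for the binned
# auxiliary comparison
draw_subsample_indices <- function(frame, period, strata, size = NULL) {
  if (is.null(size)) size <- round(nrow(frame) / 10)
  tab <- strata$table
  raw <- size * tab$Nj / strata$N
  alloc <- floor(raw)
  short <- size - sum(alloc)
  if (short > 0) {
    extra <- order(raw - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1L
  }
  R <- period_column(frame, "R", period)
  by_stratum <- split(which(R == 1L), strata$assignment[R == 1L])
  unlist(lapply(seq_len(nrow(tab)), function(j) {
    if (alloc[j] == 0L) return(integer())
    pool <- by_stratum[[as.character(tab$stratum[j])]]
    pool[sample.int(length(pool), alloc[j], replace = TRUE)]
  }), use.names = FALSE)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Occupancy analysis results\n")
  cat(sprintf("  N = %d, seed = %d\n", x$manifest$N, x$manifest$seed))
  cat("\nEstimates:\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  if (nrow(x$trends)) {
    cat("\nTrends:\n")
    print(x$trends, row.names = FALSE, digits = 4)
  }
  cat("\nDiagnostics:\n")
  print(x$diagnostics[, c("period", "N", "n", "ddc", "partial_ddc",
                          "naive_error")],
        row.names = FALSE, digits = 4)
  if (length(x$errors)) {
    cat("\nFailed components:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Writes `estimates.csv`, `trends.csv`, `diagnostics.csv`, `binned.csv`,
#' one `weights_<method>_<period>.csv` per weight-producing method, and a
#' JSON `manifest.json` echoing the seed and configuration.
#'
#' @param bundle A [run_analysis()] result.
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "results_bundle"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  utils::write.csv(bundle$estimates, file.path(outdir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$trends, file.path(outdir, "trends.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$diagnostics, file.path(outdir, "diagnostics.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$binned))
    utils::write.csv(bundle$binned, file.path(outdir, "binned.csv"),
                     row.names = FALSE)
  for (nm in names(bundle$weights))
    write_weights(bundle$weights[[nm]],
                  file.path(outdir, paste0("weights_", gsub("\\.", "_", nm),
                                           ".csv")))
  jsonlite::write_json(bundle$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
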