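## Subsampling confidence intervals. Calibration points are repeatedly
## subsampled WITHOUT replacement (node times cannot be resampled with
## replacement, so this is not a bootstrap), the tree is re-dated on each
## replicate, and per-node empirical quantiles of the replicate times give
## the intervals.

#' Subsample a calibration set
#'
#' Draws max(2, ceiling(f * k)) entries without replacement; subsets with
#' fewer than two distinct times are rejected and redrawn (bounded
#' retries).
#'
#' @param cal a `calibration_set` with k >= 3
#' @param f subsample fraction in (0, 1]
#' @param seed optional RNG seed
#' @return a `calibration_set`
#' @export
subsample_calibrations <- function(cal, f = 0.8, seed = NULL) {
  k <- nrow(cal)
  if (k < 3L) stop("CI requires >= 3 calibrations")
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  m <- max(2L, as.integer(ceiling(f * k)))
  .with_seed(seed, {
    for (try in 1:100) {
      idx <- sort(sample.int(k, m))
      if (length(unique(cal$time[idx])) >= 2L)
        return(calibration_set(cal$node[idx], cal$time[idx], cal$name[idx]))
    }
    stop("could not draw a subsample with two distinct times")
  })
}

#' Subsampling confidence intervals for node times
#'
#' @param tree a `rooted_tree`
#' @param cal a `calibration_set` (k >= 3)
#' @param n_rep number of replicates (default 100)
#' @param level interval level (default 0.95)
#' @param f subsample fraction per replicate (default 0.8)
#' @param seed master seed; replicate seeds are derived by fixed increments
#' @param ... further arguments passed to [date_tree()] (objective, s,
#'   opts, ...)
#' @return an object of class `time_ci`: list(lo, hi, level, times) where
#'   lo/hi are per-node vectors (storage position id+1) and times is the
#'   replicate-by-node matrix; quantiles use linear interpolation between
#'   order statistics (stats::quantile type 7)
#' @export
confidence_intervals <- function(tree, cal, n_rep = 100, level = 0.95,
                                 f = 0.8, seed = NULL, ...) {
  .check_tree(tree)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  times <- matrix(NA_real_, n_rep, tree$n_node)
  fails <- 0L
  for (r in seq_len(n_rep)) {
    sub <- subsample_calibrations(cal, f, seed = .child_seed(seed, r))
    d <- tryCatch(date_tree(tree, sub, ...), error = function(e) NULL)
    if (is.null(d)) { fails <- fails + 1L; next }
    times[r, ] <- d$t
  }
  if (fails > 0.2 * n_rep)
    stop(fails, "/", n_rep, " CI replicates failed")
  if (fails > 0)
    warning(fails, " CI replicate(s) failed and were dropped")
  a <- (1 - level) / 2
  lo <- apply(times, 2, stats::quantile, probs = a, na.rm = TRUE,
              names = FALSE, type = 7)
  hi <- apply(times, 2, stats::quantile, probs = 1 - a, na.rm = TRUE,
              names = FALSE, type = 7)
  structure(list(lo = lo, hi = hi, level = level, times = times),
            class = "time_ci")
}

#' @export
print.time_ci <- function(x, ...) {
  cat("Subsampling CIs at level", x$level, "over",
      sum(stats::complete.cases(x$times)), "replicates\n")
  cat("Mean width:", format(mean(x$hi - x$lo)), "\n")
  invisible(x)
}
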