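## Accuracy metrics for dated trees: height-normalized RMSE of internal
## node ages, tMRCA absolute error, per-node relative errors on the
## normalized (root = 0, height = 1) time tree, lineage-through-time
## curves, and CI coverage.

#' Height-normalized RMSE of node times
#' @param true_times,est_times numeric vectors over the same nodes
#' @param height normalization constant (> 0), typically the true tree
#'   height
#' @return sqrt(mean squared error) / height
#' @export
normalized_rmse <- function(true_times, est_times, height) {
  stopifnot(length(true_times) == length(est_times))
  if (height <= 0) stop("height must be > 0")
  sqrt(mean((est_times - true_times)^2)) / height
}

#' Absolute error of the inferred root age (tMRCA)
#' @param true_root_time,est_root_time root times
#' @return |difference|
#' @export
tmrca_error <- function(true_root_time, est_root_time) {
  abs(est_root_time - true_root_time)
}

#' Per-node relative divergence-time errors
#'
#' Computed against times normalized so the root is 0 (nodes at exactly 0,
#' i.e. the root itself, must be excluded by the caller).
#'
#' @param true_times normalized true times (> 0)
#' @param est_times estimated times on the same scale
#' @return list(per_node = |that - t|/t, mean)
#' @export
relative_node_error <- function(true_times, est_times) {
  stopifnot(length(true_times) == length(est_times))
  if (any(true_times == 0))
    stop("relative error undefined for nodes at time 0 (exclude the root)")
  e <- abs(est_times - true_times) / true_times
  list(per_node = e, mean = mean(e))
}

#' Lineage-through-time curve
#'
#' Step function of the number of extant lineages: +(children - 1) at each
#' internal node's time, -1 at each tip's time; one lineage exists before
#' the root event.
#'
#' @param dated a `dated_tree`
#' @return data frame (time, lineages): count in force from each time on
#' @export
ltt <- function(dated) {
  tr <- dated$tree
  ev_t <- dated$t
  delta <- numeric(tr$n_node)
  for (id in internal_ids(tr))
    delta[.id(id)] <- length(tr$children[[.id(id)]]) - 1L
  delta[.id(leaf_ids(tr))] <- -1
  agg <- tapply(delta, ev_t, sum)
  times <- as.numeric(names(agg))
  o <- order(times)
  data.frame(time = times[o], lineages = 1 + cumsum(as.numeric(agg)[o]))
}

#' Fraction of nodes whose true time falls inside its interval
#' @param true_times per-node true times
#' @param lo,hi interval bounds, same length
#' @return list(coverage, outside)
#' @export
ci_coverage <- function(true_times, lo, hi) {
  stopifnot(length(true_times) == length(lo), length(lo) == length(hi))
  inside <- true_times >= lo & true_times <= hi
  list(coverage = mean(inside), outside = mean(!inside))
}
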