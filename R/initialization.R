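## Feasible starting points. Each start assigns a full set of node times
## that matches every calibration exactly (so the corresponding x is in the
## null space of the constraint matrix by construction), via root-to-tip
## regression for the global rate plus a path-scaling walk that distributes
## time along root-to-calibration paths in proportion to branch length.
## Randomized starts apply the same scaling to randomly chosen clades first
## (postorder), mirroring the multiple-initial-point heuristic.

#' Root-to-tip regression
#'
#' Ordinary least squares of root-to-node distance on calibration time over
#' all calibrated nodes (leaves and, as a mild generalization, calibrated
#' internal nodes). The slope estimates the clock rate mu; the root time is
#' where the regression line crosses distance zero.
#'
#' @param tree a `rooted_tree`
#' @param cal a `calibration_set`
#' @param blen per-edge lengths (default: tree's own)
#' @return list(t0, mu, slope_ok); when the fitted slope is non-positive
#'   (no temporal signal) mu falls back to total branch length divided by
#'   the calibration time span, with a warning, and slope_ok is FALSE
#' @export
rtt_regression <- function(tree, cal, blen = NULL) {
  .check_tree(tree)
  if (is.null(blen)) blen <- tree$blen
  d <- node_depths(tree, blen)[.id(cal$node)]
  tt <- cal$time
  vt <- stats::var(tt)
  if (vt == 0) stop("all calibration times equal: rate unidentifiable")
  slope <- stats::cov(d, tt) / vt
  slope_ok <- is.finite(slope) && slope > 0
  if (!slope_ok) {
    warning("non-positive RTT slope; falling back to total-length/span rate")
    mu <- sum(blen) / (max(tt) - min(tt))
    m <- which.min(tt)
    t0 <- tt[m] - d[m] / mu
  } else {
    mu <- slope
    intercept <- mean(d) - slope * mean(tt)
    t0 <- -intercept / slope
  }
  list(t0 = t0, mu = mu, slope_ok = slope_ok)
}

## Assign times along the paths from `u` (whose time t[.id(u)] is known) to
## every already-known node inside its subtree, splitting each path's time
## span in proportion to branch lengths (zero-length paths in proportion to
## blen + btilde). Nodes are processed oldest first, which guarantees the
## attachment ancestor is never younger than the node being connected.
.assign_times_clade <- function(tree, blen, t, u, known, btilde) {
  if (!length(known)) return(t)
  ord <- known[order(t[.id(known)], known)]
  scale <- max(abs(t), na.rm = TRUE) + 1
  for (m in ord) {
    told <- t[.id(m)]
    edges <- m                             # edge ids on the path a -> m
    a <- tree$parent[.id(m)]
    while (is.na(t[.id(a)])) {
      edges <- c(edges, a)
      a <- tree$parent[.id(a)]
    }
    delta <- told - t[.id(a)]
    if (delta < -1e-9 * scale)
      warning("node ", m, " is dated older than an already-dated ",
              "ancestor (inconsistent calibrations or zero-length ",
              "edges); clamping")
    delta <- max(delta, 0)
    W <- sum(blen[edges])
    w <- if (W > 0) blen[edges] else blen[edges] + btilde
    acc <- t[.id(a)]
    for (j in rev(seq_along(edges))) {     # top-down along the path
      acc <- acc + delta * w[j] / sum(w)
      t[.id(edges[j])] <- acc
    }
    t[.id(m)] <- told                      # keep the calibration exact
  }
  t
}

## Date the clade rooted at u given already-known times inside it.
## Returns the updated time vector; u gets a time if the clade contains any
## known node (otherwise the clade is left for the nu = 1 fill).
.date_clade <- function(tree, blen, t, u, mu_glob, btilde) {
  sub <- setdiff(.subtree_ids(tree, u), u)
  known <- sub[!is.na(t[.id(sub)])]
  if (is.na(t[.id(u)])) {
    if (!length(known)) return(t)
    dep <- node_depths(tree, blen)
    d <- dep[.id(known)] - dep[.id(u)]
    tt <- t[.id(known)]
    tu <- NA_real_
    if (length(known) >= 2L && stats::var(tt) > 0) {
      slope <- stats::cov(d, tt) / stats::var(tt)
      if (is.finite(slope) && slope > 0)
        tu <- -(mean(d) - slope * mean(tt)) / slope
    }
    m1 <- order(tt, known)[1]              # oldest known, tie smallest id
    anchor <- if (d[m1] > 0) tt[m1] - d[m1] / mu_glob else tt[m1]
    if (!is.finite(tu) || tu > anchor) tu <- anchor
    ## a known ancestor (e.g. a calibrated root) bounds t_u from below;
    ## fall back to branch-length interpolation between it and the oldest
    ## known descendant
    a <- tree$parent[.id(u)]
    while (!is.na(a) && is.na(t[.id(a)])) a <- tree$parent[.id(a)]
    if (!is.na(a) && tu < t[.id(a)]) {
      ta <- t[.id(a)]
      if (ta > tt[m1] + 1e-12 * (abs(tt[m1]) + 1))
        stop("known ancestor ", a, " is younger than descendant ", known[m1])
      dep0 <- node_depths(tree, blen)
      dau <- dep0[.id(u)] - dep0[.id(a)]
      dam <- dep0[.id(known[m1])] - dep0[.id(a)]
      tu <- if (dam > 0) ta + (tt[m1] - ta) * dau / dam else ta
    }
    t[.id(u)] <- tu
  }
  .assign_times_clade(tree, blen, t, u, known, btilde)
}

#' Scale a tree's branches to match leaf times (single-start heuristic)
#'
#' The deterministic whole-tree variant of the initialization: given a root
#' time and rate from RTT, walks leaves oldest-first and splits each
#' root-to-leaf path's time span in proportion to branch lengths.
#'
#' @param tree a `rooted_tree`
#' @param leaf_times numeric vector of times for calibrated nodes, named or
#'   aligned with `nodes`
#' @param nodes integer ids the times belong to (default: all leaves)
#' @param t0 root time (e.g. from [rtt_regression()])
#' @param mu global rate (used only to fill clades without calibrations)
#' @param blen per-edge lengths (default: tree's own)
#' @param btilde smoothing constant for zero-length path splits
#' @return list(t = per-node times, tau = per-edge durations)
#' @export
scale_clade <- function(tree, leaf_times, nodes = leaf_ids(tree), t0, mu,
                        blen = NULL, btilde = smoothing_constant()) {
  .check_tree(tree)
  if (is.null(blen)) blen <- tree$blen
  stopifnot(length(leaf_times) == length(nodes))
  tmin <- min(leaf_times)
  if (t0 > tmin) stop("root time is younger than the oldest calibration")
  t <- rep(NA_real_, tree$n_node)
  t[.id(nodes)] <- leaf_times
  t <- .propagate_zero_edges(tree, blen, t)
  if (is.na(t[.id(0L)])) t[.id(0L)] <- t0
  known <- setdiff(which(!is.na(t)) - 1L, 0L)
  t <- .assign_times_clade(tree, blen, t, 0L, known, btilde)
  t <- .fill_unknown(tree, t, blen, mu)
  tau <- t[.id(seq_len(tree$n_edge))] -
    t[.id(tree$parent[.id(seq_len(tree$n_edge))])]
  list(t = t, tau = tau)
}

## A zero-length edge admits only tau = 0 in any solution recoverable from
## x (tau = nu * b / mu), so a calibration's time must hold across every
## chain of zero-length edges above it. Propagating times upward through
## zero edges before the path walk keeps the start exactly feasible even
## when noisy input lengths are truncated at zero. Nodes are processed
## oldest first; an already-set ancestor is never overwritten (two distinct
## calibration times joined by an all-zero path are genuinely degenerate
## and are left to the projection).
.propagate_zero_edges <- function(tree, blen, t) {
  known <- which(!is.na(t)) - 1L
  for (m in known[order(t[.id(known)], known)]) {
    i <- m
    repeat {
      p <- tree$parent[.id(i)]
      if (is.na(p) || blen[i] > 0 || !is.na(t[.id(p)])) break
      t[.id(p)] <- t[.id(m)]
      i <- p
    }
  }
  t
}

## nu = 1 fill for nodes untouched by any calibration path
.fill_unknown <- function(tree, t, blen, mu) {
  for (id in tree$preorder) if (id > 0L && is.na(t[.id(id)]))
    t[.id(id)] <- t[.id(tree$parent[.id(id)])] + blen[id] / mu
  t
}

## orthogonal projection onto the null space of A, via an orthonormal
## null-space basis (exact up to machine precision)
.project_feasible <- function(A, x, Z = NULL) {
  if (is.null(Z)) Z <- .null_space(A)
  as.numeric(Z %*% crossprod(Z, x))
}

#' Generate feasible starting points
#'
#' The first start is deterministic (whole-tree RTT scaling, clade set =
#' root only); the remaining n-1 pick a random set of internal nodes, date
#' each selected clade by local RTT + path scaling in postorder, then date
#' the remainder from the root. nu values are mu * tau / blen (1 on
#' zero-length edges), clipped to the nu floor and re-projected onto the
#' constraint null space if clipping occurred.
#'
#' @param tree a `rooted_tree`
#' @param cal a `calibration_set`
#' @param n number of starts (default 10)
#' @param seed master seed; per-start child seeds are derived by fixed
#'   increments
#' @param spec an `objective_spec` (supplies the nu floor and btilde)
#' @param blen per-edge lengths (default: tree's own)
#' @return list of `start_point` objects: list(nu, mu, t, S, seed, residual)
#' @export
make_start_points <- function(tree, cal, n = 10, seed = NULL,
                              spec = objective_spec(), blen = NULL) {
  .check_tree(tree)
  if (is.null(blen)) blen <- tree$blen
  if (n < 1) stop("n must be >= 1")
  rtt <- rtt_regression(tree, cal, blen)
  mu_glob <- rtt$mu
  A <- build_constraints(tree, cal, blen)$A
  Zns <- .null_space(A)
  cand <- setdiff(internal_ids(tree), 0L)
  depths_e <- node_depths(tree, rep(1, tree$n_edge))  # edge-count depth
  starts <- vector("list", n)
  for (k in seq_len(n)) {
    S <- if (k == 1L) integer(0) else .with_seed(.child_seed(seed, k), {
      size <- sample.int(max(1L, length(cand)), 1L)
      if (length(cand)) sort(sample(cand, min(size, length(cand))))
      else integer(0)
    })
    t <- rep(NA_real_, tree$n_node)
    t[.id(cal$node)] <- cal$time
    t <- .propagate_zero_edges(tree, blen, t)
    ## postorder over S (deepest first), root last
    for (u in S[order(-depths_e[.id(S)], S)])
      t <- .date_clade(tree, blen, t, u, mu_glob, spec$btilde)
    if (is.na(t[.id(0L)])) {
      known0 <- which(!is.na(t)) - 1L
      m <- known0[order(t[.id(known0)], known0)[1]]
      d0 <- root_to_node_distance(tree, m, blen)
      tm <- t[.id(m)]
      anchor <- if (d0 > 0) tm - d0 / mu_glob else tm
      t0 <- if (rtt$slope_ok && is.finite(rtt$t0)) rtt$t0 else anchor
      t[.id(0L)] <- min(t0, anchor)
    }
    t <- .date_clade(tree, blen, t, 0L, mu_glob, spec$btilde)
    t <- .fill_unknown(tree, t, blen, mu_glob)
    tau <- t[.id(seq_len(tree$n_edge))] -
      t[.id(tree$parent[.id(seq_len(tree$n_edge))])]
    nu <- ifelse(blen > 0, mu_glob * tau / blen, 1)
    x <- c(nu, mu_glob)
    ## Zero-length edges with positive duration make the per-edge relation
    ## nu * b = mu * tau unattainable, so the raw start can sit slightly
    ## off the constraint manifold; a minimum-norm projection restores
    ## A x = 0 exactly. nu values below the solver floor are left to the
    ## solver's smooth penalty ramp, which pushes them inside the bounds
    ## without leaving the null space.
    x <- .project_feasible(A, x, Zns)
    res <- max(abs(as.numeric(A %*% x)))
    starts[[k]] <- structure(list(nu = x[seq_len(tree$n_edge)],
                                  mu = x[tree$n_edge + 1L],
                                  t = t, S = S,
                                  seed = .child_seed(seed, k),
                                  residual = res),
                             class = "start_point")
  }
  starts
}
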