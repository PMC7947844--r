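## Linear calibration constraints. With x = [nu_1..nu_E, mu], every pair of
## calibrated nodes (i, j) must satisfy
##   mu (t_j - t_i) = sum_{e in P(m,j)} nu_e b_e - sum_{e in P(i,m)} nu_e b_e
## (m = MRCA of i and j). Subtracting the reference calibration's root-path
## equation from every other one leaves k-1 independent homogeneous rows
## A x = 0; shared root-path edges are cancelled exactly during construction
## (not left to float arithmetic), which also yields the sparsity the method
## relies on: O(n log n) nonzeros for random trees with all leaves dated,
## Theta(n) for caterpillar or balanced trees.

#' Build the sparse constraint system from calibrations
#'
#' The reference (anchor) calibration is the one with the minimum time,
#' ties broken by smallest node id; the choice is mathematically immaterial
#' (the null space of A is anchor-invariant).
#'
#' @param tree a `rooted_tree`
#' @param cal a `calibration_set` (k >= 2, >= 2 distinct times)
#' @param blen per-edge substitution-unit lengths (default: tree's own);
#'   raw lengths are used here -- smoothing enters only the objective
#' @return an object of class `constraint_system`: list(A, ref, cal, n_edge)
#'   where A is a (k-1) x (E+1) sparse matrix whose last column holds the
#'   mu coefficients -(t_j - t_ref)
#' @export
build_constraints <- function(tree, cal, blen = NULL) {
  .check_tree(tree)
  stopifnot(inherits(cal, "calibration_set"))
  if (is.null(blen)) blen <- tree$blen
  if (length(unique(cal$time)) < 2L)
    stop("degenerate calibrations: need two distinct times")
  E <- tree$n_edge
  ## anchor for time recovery: minimum time, ties by smallest node id
  ord_t <- order(cal$time, cal$node)
  ref <- cal$node[ord_t[1]]
  ## The k-1 independent rows are differences of CONSECUTIVE calibrations
  ## in preorder (DFS) order. Chaining neighbours (rather than subtracting
  ## one fixed anchor from everyone) keeps shared path edges short: by an
  ## Euler-tour argument the nonzero count is Theta(n) on caterpillar and
  ## balanced trees and O(n log n) in general, as the method requires. The
  ## generated row space -- hence the solution set -- is identical.
  pre_rank <- integer(tree$n_node)
  pre_rank[.id(tree$preorder)] <- seq_len(tree$n_node)
  ord <- order(pre_rank[.id(cal$node)])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(length(ord) - 1L)) {
    i0 <- cal$node[ord[r]]; t0 <- cal$time[ord[r]]
    j <- cal$node[ord[r + 1L]]; tj <- cal$time[ord[r + 1L]]
    m <- mrca_node(tree, c(j, i0))
    up <- .edges_down(tree, m, j)      # edges m -> j: +b
    dn <- .edges_down(tree, m, i0)     # edges m -> i0: -b
    ii <- c(ii, rep.int(r, length(up) + length(dn) + 1L))
    jj <- c(jj, up, dn, E + 1L)
    xx <- c(xx, blen[up], -blen[dn], -(tj - t0))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(cal) - 1L, E + 1L))
  structure(list(A = A, ref = ref, cal = cal, n_edge = E),
            class = "constraint_system")
}

#' @export
print.constraint_system <- function(x, ...) {
  cat("Constraint system:", nrow(x$A), "rows x", ncol(x$A), "columns,",
      length(x$A@x), "nonzeros; anchor node", x$ref, "\n")
  invisible(x)
}

.solution_vector <- function(x) {
  if (inherits(x, "rate_solution")) c(x$nu, x$mu) else as.numeric(x)
}

#' Constraint residual A x
#' @param system a `constraint_system`
#' @param x a `rate_solution` or a numeric vector of length E+1
#' @return numeric residual vector, one entry per constraint row
#' @export
constraint_residual <- function(system, x) {
  v <- .solution_vector(x)
  if (length(v) != ncol(system$A))
    stop("dimension mismatch: expected length ", ncol(system$A),
         ", got ", length(v))
  as.numeric(system$A %*% v)
}

## residual scaled by the overall magnitude of the constraint terms, so the
## feasibility tolerance is meaningful across time/rate scales (per-row
## scaling would over-penalize rows whose coefficients are tiny relative to
## the problem, e.g. sibling tips joined by near-zero branches)
.relative_residual <- function(system, x) {
  v <- .solution_vector(x)
  num <- max(abs(as.numeric(system$A %*% v)))
  den <- max(as.numeric(abs(system$A) %*% abs(v)), 1e-300)
  num / den
}

#' Construct a rate solution object
#' @param nu positive rate multipliers (length E)
#' @param mu positive global rate (substitutions/site/time)
#' @param objective objective value at the solution (optional)
#' @param residual max constraint residual (optional)
#' @param start start-point index this solution came from (optional)
#' @param converged logical solver flag
#' @param iterations iteration count
#' @return an object of class `rate_solution`
#' @export
rate_solution <- function(nu, mu, objective = NA_real_, residual = NA_real_,
                          start = NA_integer_, converged = NA,
                          iterations = NA_integer_) {
  structure(list(nu = as.numeric(nu), mu = as.numeric(mu),
                 objective = objective, residual = residual,
                 start = start, converged = converged,
                 iterations = iterations),
            class = "rate_solution")
}

#' @export
print.rate_solution <- function(x, ...) {
  cat("Rate solution: mu =", format(x$mu), "| objective =",
      format(x$objective), "| converged:", x$converged, "\n")
  cat("nu range: [", format(min(x$nu)), ",", format(max(x$nu)), "]\n")
  invisible(x)
}

#' Recover node times from a feasible solution
#'
#' Solves the anchor calibration's root-path equation for the root time
#' t_0 = t_ref - sum_{P(0,ref)} nu_e b_e / mu, then propagates times in
#' preorder with tau_i = nu_i b_i / mu. Zero-length edges get tau = 0
#' (t_i = t_par(i)).
#'
#' @param tree a `rooted_tree`
#' @param x a `rate_solution`
#' @param cal the `calibration_set` used to build the system
#' @param blen per-edge lengths (default: tree's own)
#' @param tol relative feasibility tolerance; an infeasible x is rejected
#' @return an object of class `dated_tree`: list(tree, t, tau, mu)
#' @export
recover_times <- function(tree, x, cal, blen = NULL, tol = 1e-6) {
  .check_tree(tree)
  if (is.null(blen)) blen <- tree$blen
  system <- build_constraints(tree, cal, blen)
  rel <- .relative_residual(system, x)
  if (is.finite(rel) && rel > tol)
    stop("solution is infeasible (relative residual ", format(rel),
         "); inspect solver diagnostics")
  v <- .solution_vector(x)
  nu <- v[seq_len(tree$n_edge)]; mu <- v[tree$n_edge + 1L]
  if (mu <= 0) stop("recover_times requires mu > 0")
  tau <- nu * blen / mu
  ref_path <- .edges_down(tree, 0L, system$ref)
  t_ref <- cal$time[cal$node == system$ref][1]
  t0 <- t_ref - sum(tau[ref_path])
  t <- numeric(tree$n_node)
  t[.id(0L)] <- t0
  for (id in tree$preorder) if (id > 0L)
    t[.id(id)] <- t[.id(tree$parent[.id(id)])] + tau[id]
  dated_tree(tree, t, mu = mu)
}

#' Construct a dated tree
#' @param tree a `rooted_tree`
#' @param t per-node times by storage position (id+1)
#' @param mu the global rate used (optional)
#' @return an object of class `dated_tree`
#' @export
dated_tree <- function(tree, t, mu = NA_real_) {
  .check_tree(tree)
  stopifnot(length(t) == tree$n_node)
  tau <- numeric(tree$n_edge)
  for (id in seq_len(tree$n_edge))
    tau[id] <- t[.id(id)] - t[.id(tree$parent[.id(id)])]
  structure(list(tree = tree, t = as.numeric(t), tau = tau,
                 mu = mu), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated tree:", x$tree$n_leaf, "leaves | root time",
      format(x$t[1]), "| height", format(tree_height(x)), "\n")
  if (is.finite(x$mu)) cat("Clock rate mu =", format(x$mu), "\n")
  invisible(x)
}

#' Height of a dated tree
#'
#' The latest leaf time minus the root time.
#'
#' @param dated a `dated_tree`
#' @return a non-negative number
#' @export
tree_height <- function(dated) {
  stopifnot(inherits(dated, "dated_tree"))
  max(dated$t[.id(leaf_ids(dated$tree))]) - dated$t[1]
}
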