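## Constrained minimization. The linear equality constraints A x = 0 are
## eliminated exactly: a QR factorization of t(A) yields an orthonormal
## basis Z of the null space, and the solver works on x = x0 + Z y with x0
## a feasible start, so every iterate satisfies the calibrations to machine
## precision. The reduced problem is smooth and bound-free except for
## positivity of nu (and mu), which is enforced by a large finite penalty
## ramp outside the bounds; the log-based objectives diverge at nu -> 0+
## anyway. L-BFGS-B with the analytic gradient does the minimization.

#' Solver options
#' @param n_starts number of feasible starting points (default 10)
#' @param seed master RNG seed for the randomized starts
#' @param feas_tol max relative constraint residual accepted (default 1e-8)
#' @param obj_tol convergence tolerance on the objective change
#'   (default 1e-10, relative)
#' @param max_iter iteration cap (default 5000)
#' @param mu_floor lower bound on mu (default 1e-12)
#' @return list of class `solve_options`
#' @export
solve_options <- function(n_starts = 10, seed = NULL, feas_tol = 1e-8,
                          obj_tol = 1e-10, max_iter = 5000,
                          mu_floor = 1e-12) {
  stopifnot(n_starts >= 1, feas_tol > 0, obj_tol > 0, max_iter >= 1)
  structure(list(n_starts = n_starts, seed = seed, feas_tol = feas_tol,
                 obj_tol = obj_tol, max_iter = max_iter,
                 mu_floor = mu_floor), class = "solve_options")
}

.null_space <- function(A) {
  ## row-normalize so rank detection is scale-free (null space unchanged)
  rn <- sqrt(Matrix::rowSums(A^2))
  A <- A[rn > 0, , drop = FALSE] / rn[rn > 0]
  At <- as.matrix(Matrix::t(A))
  qrA <- qr(At, tol = 1e-12)
  r <- qrA$rank
  Q <- qr.Q(qrA, complete = TRUE)
  if (r >= ncol(Q)) stop("constraint system leaves no degrees of freedom")
  Q[, seq.int(r + 1L, ncol(Q)), drop = FALSE]
}

#' Minimize an objective subject to the calibration constraints
#'
#' @param spec an `objective_spec`
#' @param system a `constraint_system`
#' @param x0 a feasible `start_point` (from [make_start_points()])
#' @param blen per-edge substitution-unit lengths
#' @param opts a `solve_options`
#' @param Z optional precomputed null-space basis of system$A
#' @return a `rate_solution`; `converged = FALSE` flags solver failure
#'   (never silently dropped)
#' @export
minimize_constrained <- function(spec, system, x0, blen,
                                 opts = solve_options(), Z = NULL) {
  E <- system$n_edge
  x_start <- c(x0$nu, x0$mu)
  if (.relative_residual(system, x_start) > opts$feas_tol)
    stop("infeasible starting point (residual ", format(x0$residual), ")")
  if (is.null(Z)) Z <- .null_space(system$A)
  lo <- c(rep(spec$nu_floor, E), opts$mu_floor)
  ## bounds via a continuous clamped-objective + quadratic penalty: below
  ## the floor the objective is evaluated at the clamped point and a
  ## BIG * violation^2 term takes over (objective and gradient both
  ## continuous across the boundary)
  BIG <- 1e10
  fn <- function(y) {
    x <- x_start + as.numeric(Z %*% y)
    viol <- pmax(lo - x, 0)
    objective_value(pmax(x, lo), spec, blen) + BIG * sum(viol^2)
  }
  gr <- function(y) {
    x <- x_start + as.numeric(Z %*% y)
    viol <- pmax(lo - x, 0)
    g <- objective_gradient(pmax(x, lo), spec, blen)
    g[viol > 0] <- 0
    as.numeric(crossprod(Z, g - 2 * BIG * viol))
  }
  start_idx <- if (is.null(x0$start_index)) NA_integer_ else x0$start_index
  y0 <- numeric(ncol(Z))
  res <- tryCatch(
    stats::optim(y0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = opts$max_iter,
                                factr = opts$obj_tol / .Machine$double.eps,
                                pgtol = 0)),
    error = function(e) NULL)
  if (is.null(res)) {
    sol <- rate_solution(x0$nu, x0$mu,
                         objective = tryCatch(
                           objective_value(x_start, spec, blen),
                           error = function(e) Inf),
                         residual = .relative_residual(system, x_start),
                         start = start_idx, converged = FALSE,
                         iterations = 0L)
    return(sol)
  }
  x <- x_start + as.numeric(Z %*% res$par)
  rel <- .relative_residual(system, x)
  ## optim can report an abnormal line-search exit at a point that is
  ## already stationary; a near-zero reduced gradient is accepted as
  ## convergence evidence
  gnorm <- max(abs(gr(res$par)))
  conv_code_ok <- res$convergence == 0 ||
    gnorm <= 1e-4 * (1 + abs(res$value))
  ## the penalty equilibrium can leave nu a hair below the floor (depth
  ## ~ |gradient| / BIG); anything materially below the bounds means the
  ## bounded problem was not solved and the run must not count as converged
  bounds_ok <- all(x >= lo - 0.5 * c(rep(spec$nu_floor, E), 0) - 1e-12)
  x <- pmax(x, c(rep(1e-12, E), opts$mu_floor))
  rate_solution(x[seq_len(E)], x[E + 1L],
                objective = objective_value(pmax(x, lo), spec, blen),
                residual = rel,
                start = start_idx,
                converged = conv_code_ok && rel <= opts$feas_tol &&
                  bounds_ok,
                iterations = res$counts[["function"]])
}

#' Date a rooted tree
#'
#' Top-level interface: builds the calibration constraint system, generates
#' multiple feasible starting points, minimizes the chosen objective from
#' each, selects the best converged feasible run (lowest objective, ties by
#' lowest start index), and recovers node times.
#'
#' @param tree a `rooted_tree` with branch lengths in expected
#'   substitutions per site
#' @param cal a `calibration_set` (>= 2 points, >= 2 distinct times)
#' @param objective one of "wlogdate" (default), "logdate", "lf", "lsd"
#' @param s sequence length in sites (default 1000)
#' @param alpha no-event probability level for the smoothing constant
#' @param weights wlogdate weighting variant: "sqrt" (default) or "linear"
#' @param opts a `solve_options` (n_starts, seed, tolerances)
#' @param blen per-edge lengths overriding the tree's own
#' @return a `dated_tree` with extra fields: `solution` (the selected
#'   `rate_solution`), `report` (per-start data frame), `objective_scheme`
#' @examples
#' tr <- parse_newick("((A:0.01,B:0.02):0.01,C:0.02);")
#' cal <- parse_date_file("3\nA 2\nB 3\nC 2", tr)
#' dt <- date_tree(tr, cal, opts = solve_options(n_starts = 2, seed = 1))
#' dt$t
#' @export
date_tree <- function(tree, cal,
                      objective = c("wlogdate", "logdate", "lf", "lsd"),
                      s = 1000, alpha = 0.01,
                      weights = c("sqrt", "linear"),
                      opts = solve_options(), blen = NULL) {
  .check_tree(tree)
  if (is.null(blen)) blen <- tree$blen
  spec <- objective_spec(match.arg(objective), s = s, alpha = alpha,
                         weights = match.arg(weights))
  system <- build_constraints(tree, cal, blen)
  starts <- make_start_points(tree, cal, n = opts$n_starts,
                              seed = opts$seed, spec = spec, blen = blen)
  Z <- .null_space(system$A)
  runs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    starts[[k]]$start_index <- k
    runs[[k]] <- minimize_constrained(spec, system, starts[[k]], blen,
                                      opts, Z = Z)
  }
  report <- data.frame(
    start = seq_along(runs),
    objective = vapply(runs, function(r) r$objective, 0),
    residual = vapply(runs, function(r) r$residual, 0),
    converged = vapply(runs, function(r) isTRUE(r$converged), TRUE),
    iterations = vapply(runs, function(r) as.integer(r$iterations), 0L))
  ok <- which(report$converged)
  if (!length(ok)) {
    ## fall back to feasible non-converged runs only if nothing converged
    ok <- which(report$residual <= opts$feas_tol)
    if (!length(ok)) {
      print(report)
      stop("no feasible run; see per-start diagnostics above")
    }
  }
  best <- ok[which.min(report$objective[ok])]
  sol <- runs[[best]]
  dated <- recover_times(tree, sol, cal, blen = blen,
                         tol = max(opts$feas_tol * 10, 1e-6))
  dated$solution <- sol
  dated$report <- report
  dated$objective_scheme <- spec$scheme
  dated
}

#' Per-node report table for a dated tree
#' @param dated a `dated_tree`
#' @param ci optional result of [confidence_intervals()]
#' @return data frame with node, label, time (and lo/hi when ci is given)
#' @export
dated_report <- function(dated, ci = NULL) {
  tr <- dated$tree
  out <- data.frame(node = seq_len(tr$n_node) - 1L,
                    label = tr$label,
                    time = dated$t)
  if (!is.null(ci)) { out$lo <- ci$lo; out$hi <- ci$hi }
  out
}

#' Write a dated tree as a time-unit newick with date annotations
#' @param dated a `dated_tree`
#' @param path optional output file; when NULL the string is returned
#' @return the newick string, invisibly when written to a file
#' @export
write_dated_newick <- function(dated, path = NULL) {
  ann <- sprintf("[&date=%.10g]", dated$t)
  s <- write_newick(dated$tree, lengths = pmax(dated$tau, 0),
                    node_annotations = ann)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
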