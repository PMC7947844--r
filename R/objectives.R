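## Objective functions on x = [nu, mu]. All four schemes are mu-free (mu
## enters only through the constraints):
##   lf       : sum_i b_i (nu_i - log nu_i)        (Poisson substitution count)
##   lsd      : sum_i b_i (1 - nu_i)^2             (Gaussian branch error)
##   logdate  : sum_i log^2 nu_i                   (symmetry of ratios)
##   wlogdate : sum_i w_i log^2 nu_i  with w_i = sqrt(b_i + btilde) (default)
##              or w_i = b_i + btilde (linear variant)
## btilde = -log(1 - alpha) / s is the longest branch expected to produce no
## substitutions with probability >= 1 - alpha on an s-site alignment; it
## floors the weights so that zero-event branches (whose reported lengths
## are arbitrary) cannot dominate.

#' Smoothing constant for short-branch weights
#' @param s sequence length in sites (>= 1)
#' @param alpha no-event probability level in (0, 1)
#' @return btilde = -log(1 - alpha) / s
#' @export
smoothing_constant <- function(s = 1000, alpha = 0.01) {
  if (s < 1) stop("s must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  -log(1 - alpha) / s
}

#' Per-edge weights for wLogDate
#' @param blen per-edge substitution-unit lengths (>= 0)
#' @param btilde smoothing constant (see [smoothing_constant()])
#' @param variant "sqrt" (default): sqrt(blen + btilde); "linear":
#'   blen + btilde
#' @return strictly positive weight vector, monotone in blen
#' @export
edge_weights <- function(blen, btilde, variant = c("sqrt", "linear")) {
  variant <- match.arg(variant)
  if (any(blen < 0)) stop("negative branch length")
  if (btilde <= 0) stop("btilde must be > 0")
  if (variant == "sqrt") sqrt(blen + btilde) else blen + btilde
}

#' Objective specification
#'
#' @param scheme one of "wlogdate", "logdate", "lf", "lsd"
#' @param s sequence length (default 1000)
#' @param alpha no-event probability level (default 0.01)
#' @param weights weighting variant for wlogdate ("sqrt" default, "linear")
#' @param nu_floor solver lower bound on nu (default 1e-5)
#' @return an object of class `objective_spec`
#' @export
objective_spec <- function(scheme = c("wlogdate", "logdate", "lf", "lsd"),
                           s = 1000, alpha = 0.01,
                           weights = c("sqrt", "linear"),
                           nu_floor = 1e-5) {
  scheme <- match.arg(scheme)
  weights <- match.arg(weights)
  if (nu_floor <= 0) stop("nu_floor must be > 0")
  structure(list(scheme = scheme, s = s, alpha = alpha,
                 btilde = smoothing_constant(s, alpha),
                 weights = weights, nu_floor = nu_floor),
            class = "objective_spec")
}

.obj_w <- function(spec, blen) {
  switch(spec$scheme,
         wlogdate = edge_weights(blen, spec$btilde, spec$weights),
         logdate  = rep(1, length(blen)),
         NULL)
}

.check_nu <- function(nu) {
  if (any(nu <= 0)) stop("objective undefined for nu <= 0")
  nu
}

#' Objective value
#' @param x a `rate_solution` or numeric vector c(nu, mu)
#' @param spec an `objective_spec`
#' @param blen per-edge substitution-unit lengths
#' @return a number
#' @export
objective_value <- function(x, spec, blen) {
  v <- .solution_vector(x)
  nu <- .check_nu(v[seq_along(blen)])
  switch(spec$scheme,
         lf  = sum(blen * (nu - log(nu))),
         lsd = sum(blen * (1 - nu)^2),
         sum(.obj_w(spec, blen) * log(nu)^2))
}

#' Objective gradient (length E+1; the mu component is identically zero)
#' @inheritParams objective_value
#' @return numeric vector of length E+1
#' @export
objective_gradient <- function(x, spec, blen) {
  v <- .solution_vector(x)
  nu <- .check_nu(v[seq_along(blen)])
  g <- switch(spec$scheme,
              lf  = blen * (1 - 1 / nu),
              lsd = 2 * blen * (nu - 1),
              2 * .obj_w(spec, blen) * log(nu) / nu)
  c(g, 0)
}

#' Diagonal of the objective Hessian (length E+1; mu entry zero)
#'
#' For the log schemes H_ii = 2 w_i (1 - log nu_i) / nu_i^2: positive for
#' nu_i < e, zero at nu_i = e, negative beyond (the problem is convex only
#' on 0 < nu <= e). LF and LSD diagonals are positive everywhere.
#'
#' @inheritParams objective_value
#' @return numeric vector of length E+1
#' @export
objective_hessian_diag <- function(x, spec, blen) {
  v <- .solution_vector(x)
  nu <- .check_nu(v[seq_along(blen)])
  h <- switch(spec$scheme,
              lf  = blen / nu^2,
              lsd = 2 * blen,
              2 * .obj_w(spec, blen) * (1 - log(nu)) / nu^2)
  c(h, 0)
}

#' Skewness comparison of per-branch penalty terms
#'
#' Diagnostic for the symmetry-of-ratios argument: draws rate multipliers r
#' from a LogNormal with mean 1 and the given sd, sets b = r * mu_tau, draws
#' estimated lengths bhat ~ Normal(b, sqrt(b/s)) (truncated at a small
#' positive floor), and compares the skewness of the least-squares penalty
#' term mu_tau/bhat - 1 with that of the log penalty log(mu_tau/bhat).
#'
#' @param n_draws number of compound draws
#' @param mu_tau the fixed expected branch length mu * tau
#' @param s sequence length controlling the error variance
#' @param sd_rate sd of the LogNormal rate multiplier (mean 1)
#' @param seed optional RNG seed
#' @return list(skew_logdate, skew_lsd) of sample skewnesses
#' @export
penalty_skewness <- function(n_draws = 50000, mu_tau = 0.1, s = 200,
                             sd_rate = 0.4, seed = NULL) {
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + sd_rate^2))
    r <- stats::rlnorm(n_draws, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    b <- r * mu_tau
    bhat <- stats::rnorm(n_draws, mean = b, sd = sqrt(b / s))
    bhat <- pmax(bhat, 1e-8)
    list(skew_logdate = .skewness(log(mu_tau / bhat)),
         skew_lsd = .skewness(mu_tau / bhat - 1))
  })
}

.skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
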