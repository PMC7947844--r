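test_that("smoothing constant", {
  expect_equal(smoothing_constant(1000, 0.01), -log(0.99) / 1000)
  expect_equal(smoothing_constant(1000, 0.01), 1.00503e-5,
               tolerance = 1e-5)
  expect_equal(smoothing_constant(100, 0.01),
               10 * smoothing_constant(1000, 0.01))
  expect_lt(smoothing_constant(1000, 1e-9), 1e-11)   # alpha -> 0 limit
  expect_error(smoothing_constant(1000, 0), "alpha")
  expect_error(smoothing_constant(1000, 1), "alpha")
  expect_error(smoothing_constant(0, 0.5), "s must")
})

test_that("edge weights", {
  bt <- smoothing_constant()
  b <- c(0, 1e-4, 0.01, 0.3)
  w <- edge_weights(b, bt)
  expect_equal(w[1], sqrt(bt))
  expect_true(all(diff(w) > 0))             # monotone in b
  expect_equal(w^2 - bt, b)                 # algebraic inversion
  wl <- edge_weights(b, bt, "linear")
  expect_equal(wl, b + bt)
  expect_error(edge_weights(c(-1, 1), bt), "negative")
})

test_that("objective values at reference points", {
  b <- c(0.01, 0.02, 0.03, 0.04)
  x1 <- c(rep(1, 4), 0.01)
  for (sch in c("logdate", "wlogdate", "lsd"))
    expect_equal(objective_value(x1, objective_spec(sch), b), 0)
  expect_equal(objective_value(x1, objective_spec("lf"), b), sum(b))

  # symmetry of ratios for the unweighted scheme: nu and 1/nu cost the same
  sp <- objective_spec("logdate")
  x4 <- c(4, 1, 1, 1, 0.01)
  xq <- c(1 / 4, 1, 1, 1, 0.01)
  expect_equal(objective_value(x4, sp, b), objective_value(xq, sp, b))
  expect_equal(objective_value(x4, sp, b), log(4)^2)
  expect_equal(log(4)^2, 1.9218, tolerance = 1e-4)

  # LSD penalizes the same ratio asymmetrically, by a factor > 10
  lsd <- objective_spec("lsd")
  r <- objective_value(x4, lsd, b) / objective_value(xq, lsd, b)
  expect_equal(r, 16)
  expect_gt(r, 10)

  expect_error(objective_value(c(-1, 1, 1, 1, 0.01), sp, b), "nu <= 0")
  # LF is bounded below by sum(b), attained at nu = 1
  set.seed(2)
  for (k in 1:20)
    expect_gte(objective_value(c(runif(4, 0.1, 5), 0.01),
                               objective_spec("lf"), b), sum(b))
})

test_that("analytic gradient matches central differences", {
  set.seed(11)
  for (k in 1:100) {
    E <- sample(3:8, 1)
    b <- runif(E, 1e-4, 0.2)
    x <- c(runif(E, 0.2, 3), runif(1, 1e-3, 0.1))
    sch <- sample(c("wlogdate", "logdate", "lf", "lsd"), 1)
    sp <- objective_spec(sch)
    g <- objective_gradient(x, sp, b)
    expect_equal(g[E + 1], 0)               # mu component always zero
    h <- 1e-6
    for (i in sample(E, 2)) {
      xp <- x; xm <- x
      xp[i] <- x[i] + h; xm[i] <- x[i] - h
      fd <- (objective_value(xp, sp, b) - objective_value(xm, sp, b)) /
        (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
  # gradient is zero at nu = 1 and has the sign of log(nu)
  b <- c(0.01, 0.02, 0.03)
  sp <- objective_spec("wlogdate")
  expect_equal(objective_gradient(c(1, 1, 1, 0.01), sp, b), rep(0, 4))
  g <- objective_gradient(c(2, 0.5, 1, 0.01), sp, b)
  expect_gt(g[1], 0)
  expect_lt(g[2], 0)
})

test_that("Hessian diagonal: formula, convexity boundary, differences", {
  b <- c(0.01, 0.05, 0.2)
  sp <- objective_spec("wlogdate")
  w <- edge_weights(b, sp$btilde)
  expect_equal(objective_hessian_diag(c(1, 1, 1, 0.01), sp, b),
               c(2 * w, 0))
  # zero exactly at nu = e, negative beyond
  he <- objective_hessian_diag(c(exp(1), 1, 1, 0.01), sp, b)
  expect_equal(he[1], 0, tolerance = 1e-12)
  hb <- objective_hessian_diag(c(exp(1) + 0.5, 1, 1, 0.01), sp, b)
  expect_lt(hb[1], 0)
  # finite-difference second derivative
  set.seed(21)
  for (k in 1:20) {
    x <- c(runif(3, 0.3, 2.5), 0.01)
    sch <- sample(c("wlogdate", "lf", "lsd"), 1)
    spk <- objective_spec(sch)
    hh <- objective_hessian_diag(x, spk, b)
    h <- 1e-4
    i <- sample(3, 1)
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    fd <- (objective_value(xp, spk, b) - 2 * objective_value(x, spk, b) +
             objective_value(xm, spk, b)) / h^2
    expect_equal(hh[i], fd, tolerance = 1e-3)
  }
  # LF and LSD are convex over nu > 0
  for (sch in c("lf", "lsd")) {
    spk <- objective_spec(sch)
    for (k in 1:10) {
      x <- c(runif(3, 0.05, 10), 0.01)
      expect_true(all(objective_hessian_diag(x, spk, b)[1:3] > 0))
    }
  }
})

test_that("log penalty terms are less skewed than least-squares terms", {
  sk <- penalty_skewness(n_draws = 20000, mu_tau = 0.1, s = 200, seed = 5)
  expect_lt(abs(sk$skew_logdate), abs(sk$skew_lsd))
})
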