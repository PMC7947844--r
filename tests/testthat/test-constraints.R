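test_that("toy constraint system has the documented rows", {
  tr <- toy_tree()
  cal <- toy_cal(tr)
  sys <- build_constraints(tr, cal)
  A <- as.matrix(sys$A)
  expect_equal(dim(A), c(2L, 5L))
  # anchor = minimum time, tie by smallest node id -> leaf A (id 2)
  expect_equal(sys$ref, node_by_label(tr, "A"))
  # row for B: paths from mrca(A,B)=u, so the shared root edge cancels:
  # +b_B on B's column, -b_A on A's column, -(3-2) in the mu column
  rB <- A[which(abs(A[, 5] + 1) < 1e-12), ]
  expect_equal(rB[node_by_label(tr, "B")], 0.02)
  expect_equal(rB[node_by_label(tr, "A")], -0.01)
  expect_equal(rB[1], 0)  # edge of u cancelled exactly
})

test_that("k calibrations give exactly k-1 rows", {
  truth <- simulate_birth_death_tree(8, 1, 0.4, sampling = "periodic",
                                     seed = 3)
  tr <- truth$tree
  lv <- leaf_ids(tr)[1:5]
  cal <- calibration_set(lv, truth$t[lv + 1L])
  expect_equal(nrow(build_constraints(tr, cal)$A), 4L)
})

test_that("the k-1 rows imply every pairwise constraint", {
  for (seed in 1:50) {
    n <- sample(4:12, 1)
    truth <- simulate_birth_death_tree(n, 1, 0.4, sampling = "periodic",
                                       seed = seed)
    tr <- truth$tree
    mu <- 0.02
    tr$blen <- mu * pmax(truth$tau, 0)          # strict clock: x feasible
    lv <- leaf_ids(tr)
    cal <- calibration_set(lv, truth$t[lv + 1L])
    x <- c(rep(1, tr$n_edge), mu)
    sys <- build_constraints(tr, cal)
    expect_lt(max(abs(constraint_residual(sys, x))), 1e-9)
    # brute-force check of psi(i,j) over all calibrated pairs
    for (i in lv) for (j in lv) if (i < j) {
      m <- mrca_node(tr, c(i, j))
      up <- walk_root_path_sum(tr, j, tr$blen) -
        walk_root_path_sum(tr, m, tr$blen)
      dn <- walk_root_path_sum(tr, i, tr$blen) -
        walk_root_path_sum(tr, m, tr$blen)
      psi <- mu * (truth$t[j + 1L] - truth$t[i + 1L]) - (up - dn)
      expect_lt(abs(psi), 1e-9)
    }
  }
})

test_that("residual mechanics: homogeneity, zero vector, dense oracle", {
  tr <- toy_tree()
  sys <- build_constraints(tr, toy_cal(tr))
  expect_equal(constraint_residual(sys, rep(0, 5)), c(0, 0))
  expect_equal(constraint_residual(sys, c(1, 1, 1, 1, 0.01)), c(0, 0))
  set.seed(4)
  for (k in 1:20) {
    x <- rnorm(5)
    dense <- as.numeric(as.matrix(sys$A) %*% x)
    expect_equal(constraint_residual(sys, x), dense, tolerance = 1e-12)
    expect_equal(constraint_residual(sys, 3.7 * x), 3.7 * dense,
                 tolerance = 1e-12)
  }
  expect_error(constraint_residual(sys, rep(1, 4)), "dimension mismatch")
})

test_that("anchor choice does not change the solution set", {
  tr <- toy_tree()
  cal_a <- calibration_set(c(2L, 3L, 4L), c(2, 3, 2))
  # same constraints with a different entry order / implied anchor tie
  cal_b <- calibration_set(c(4L, 3L, 2L), c(2, 3, 2))
  Za <- logdater:::.null_space(build_constraints(tr, cal_a)$A)
  Zb <- logdater:::.null_space(build_constraints(tr, cal_b)$A)
  # compare projectors onto the null spaces
  expect_equal(Za %*% t(Za), Zb %*% t(Zb), tolerance = 1e-10)
})

test_that("sparsity: Theta(n) on a balanced tree, O(n log n) randomly", {
  balanced <- function(depth) {
    lab <- function(k) paste0("L", k)
    build <- function(d, off) {
      if (d == 0) return(paste0(lab(off), ":1"))
      paste0("(", build(d - 1, 2 * off), ",", build(d - 1, 2 * off + 1),
             "):1")
    }
    parse_newick(paste0(build(depth, 1), ";"))
  }
  for (depth in 4:7) {
    tr <- balanced(depth)
    n <- tr$n_leaf
    d <- node_depths(tr)
    cal <- calibration_set(leaf_ids(tr), d[leaf_ids(tr) + 1L] +
                             seq_len(n) * 1e-6)
    nz <- length(build_constraints(tr, cal)$A@x)
    expect_lt(nz, 6 * n)
  }
  for (seed in 1:5) {
    tr <- random_tree(64, seed + 70)
    n <- tr$n_leaf
    d <- node_depths(tr)
    cal <- calibration_set(leaf_ids(tr), d[leaf_ids(tr) + 1L])
    nz <- length(build_constraints(tr, cal)$A@x)
    expect_lt(nz, 6 * n * log2(n))
  }
})

test_that("recover_times: strict clock, zero edges, identity audit", {
  tr <- toy_tree()
  cal <- toy_cal(tr)
  sol <- rate_solution(rep(1, 4), 0.01)
  d <- recover_times(tr, sol, cal)
  expect_equal(d$t, c(0, 1, 2, 3, 2), tolerance = 1e-9)
  expect_equal(d$mu, 0.01)
  expect_equal(tree_height(d), 3, tolerance = 1e-9)

  # zero-length edge forces tau = 0, t_i = t_par(i)
  tr0 <- parse_newick("((A:0.0,B:0.02):0.01,C:0.02);")
  cal0 <- parse_date_file("3\nA 1.0\nB 3.0\nC 2.0", tr0)
  sol0 <- local({
    st <- make_start_points(tr0, cal0, n = 1)[[1]]
    rate_solution(st$nu, st$mu)
  })
  d0 <- recover_times(tr0, sol0, cal0)
  idA <- node_by_label(tr0, "A")
  expect_equal(d0$tau[idA], 0)
  expect_equal(d0$t[idA + 1L], d0$t[tr0$parent[idA + 1L] + 1L])

  # per-edge identity on a random feasible solution
  inst <- strict_instance(10, seed = 8)
  stp <- make_start_points(inst$tree, inst$cal, n = 3, seed = 2)[[3]]
  dd <- recover_times(inst$tree, rate_solution(stp$nu, stp$mu), inst$cal)
  for (e in seq_len(inst$tree$n_edge))
    expect_equal(dd$t[e + 1L] - dd$t[inst$tree$parent[e + 1L] + 1L],
                 dd$tau[e], tolerance = 1e-9)
  # calibrated nodes reproduce their times
  expect_lt(max(abs(dd$t[inst$cal$node + 1L] - inst$cal$time)), 1e-8)

  # infeasible x is rejected
  bad <- rate_solution(runif(4, 0.5, 2), 0.01)
  expect_error(recover_times(tr, bad, cal), "infeasible")
})
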