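test_that("birth-death simulator: sampling modes and reproducibility", {
  d <- simulate_birth_death_tree(20, 1, 0.5, sampling = "ultrametric",
                                 seed = 3)
  lt <- d$t[leaf_ids(d$tree) + 1L]
  expect_equal(d$tree$n_leaf, 20L)
  expect_lt(diff(range(lt)), 1e-9)
  expect_equal(d$t[1], 0)                       # root at time 0

  dp <- simulate_birth_death_tree(20, 1, 0.5, sampling = "periodic",
                                  seed = 3)
  ltp <- dp$t[leaf_ids(dp$tree) + 1L]
  expect_equal(dp$tree$n_leaf, 20L)
  expect_gt(length(unique(round(ltp, 9))), 1L)  # heterochronous
  expect_true(all(dp$tau >= 0))

  again <- simulate_birth_death_tree(20, 1, 0.5, sampling = "periodic",
                                     seed = 3)
  expect_identical(dp$t, again$t)
  other <- simulate_birth_death_tree(20, 1, 0.5, sampling = "periodic",
                                     seed = 4)
  expect_false(identical(dp$t, other$t))
  expect_error(simulate_birth_death_tree(2, 1, 0.5), "n must be >= 3")
  expect_error(simulate_birth_death_tree(5, 0.5, 1), "birth > death")
})

test_that("faster birth reaches the target tip count sooner", {
  height_at <- function(birth, seed)
    tree_height(simulate_birth_death_tree(15, birth, 0.2,
                                          sampling = "ultrametric",
                                          seed = seed))
  slow <- vapply(1:40, function(s) height_at(0.5, s), 0)
  fast <- vapply(1:40, function(s) height_at(2, s), 0)
  expect_lt(mean(fast), mean(slow))
})

test_that("rate models have the stated moments", {
  big <- simulate_birth_death_tree(600, 1, 0.3, sampling = "ultrametric",
                                   seed = 5)
  E <- big$tree$n_edge

  r <- draw_rates(big, rate_model("strict"), seed = 1)
  expect_true(all(r == 0.006))

  x <- draw_rates(big, rate_model("lognormal"), seed = 2) / 0.006
  se <- sd(x) / sqrt(E)
  expect_lt(abs(mean(x) - 1), 3 * se)
  expect_lt(abs(sd(x) - 0.4), 0.08)

  g <- draw_rates(big, rate_model("gamma"), seed = 3) / 0.006
  expect_lt(abs(mean(g) - 1), 3 * sd(g) / sqrt(E))
  expect_lt(abs(var(g) - 1 / 6.05), 0.05)

  e <- draw_rates(big, rate_model("exponential"), seed = 4) / 0.006
  expect_lt(abs(mean(e) - 1), 3 * sd(e) / sqrt(E))

  a <- draw_rates(big, rate_model("autocorrelated"), seed = 6)
  expect_true(all(a > 0))
  # adjacent edges are positively correlated under the Brownian log-rate
  kid_pairs <- do.call(rbind, lapply(internal_ids(big$tree), function(i) {
    ch <- big$tree$children[[i + 1L]]
    if (length(ch) == 2 && all(ch > 0)) ch else NULL
  }))
  expect_gt(cor(log(a[kid_pairs[, 1]]), log(a[kid_pairs[, 2]])), 0.2)
})

test_that("true branch lengths and noise models", {
  tr <- toy_tree()
  d <- dated_tree(tr, c(0, 1, 2, 3, 2))
  b <- true_branch_lengths(d, rep(0.01, 4))
  expect_equal(b, c(0.01, 0.01, 0.02, 0.02))
  d0 <- dated_tree(tr, c(0, 1, 1, 3, 2))      # zero-duration edge
  expect_equal(true_branch_lengths(d0, rep(0.01, 4))[2], 0)

  expect_equal(add_branch_noise(b, noise_model("none")), b)
  bb <- rep(0.02, 10000)
  po <- add_branch_noise(bb, noise_model("poisson", s = 1000), seed = 2)
  expect_equal(po, round(po * 1000) / 1000)    # lattice of counts / s
  expect_lt(abs(mean(po) - 0.02),
            3 * sqrt(0.02 / 1000) / sqrt(10000))
  expect_true(all(add_branch_noise(rep(0, 50),
                                   noise_model("poisson", 1000),
                                   seed = 1) == 0))
  ga <- add_branch_noise(bb, noise_model("gaussian", s = 1000), seed = 3)
  expect_true(all(ga >= 0))
  expect_lt(abs(mean(ga) - 0.02), 3 * sqrt(0.02 / 1000) / sqrt(10000))
  # relative spread grows as branches shrink (sd ~ 1/sqrt(b s))
  s_small <- sd(add_branch_noise(rep(0.001, 5000),
                                 noise_model("gaussian", 1000),
                                 seed = 4) / 0.001)
  s_big <- sd(add_branch_noise(rep(0.1, 5000),
                               noise_model("gaussian", 1000),
                               seed = 4) / 0.1)
  expect_gt(s_small, 5 * s_big)
})

test_that("JC sequence simulation follows the model", {
  tr <- toy_tree()
  aln0 <- simulate_jc_sequences(tr, b = rep(0, 4), s = 200, seed = 1)
  expect_true(all(aln0[1, ] == aln0[2, ]) && all(aln0[1, ] == aln0[3, ]))

  # two-leaf tree with total path b = 0.1: expected p-distance
  two <- parse_newick("(A:0.06,B:0.04);")
  aln <- simulate_jc_sequences(two, s = 10000, seed = 7)
  p <- mean(aln["A", ] != aln["B", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_equal(p_exp, 0.09362, tolerance = 1e-4)
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  # stationary uniform base composition at the tips
  aln2 <- simulate_jc_sequences(two, s = 10000, seed = 8)
  counts <- table(factor(aln2, levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("fixed-topology JC ML branch lengths", {
  # two-taxon closed form
  two <- parse_newick("(A:0.05,B:0.05);")
  aln <- simulate_jc_sequences(two, s = 5000, seed = 9)
  p <- mean(aln["A", ] != aln["B", ])
  bh <- estimate_branch_lengths_jc(two, aln)
  expect_equal(sum(bh), -0.75 * log(1 - 4 * p / 3), tolerance = 1e-9)
  # identical sequences give zero lengths
  same <- matrix("A", 2, 100, dimnames = list(c("A", "B"), NULL))
  expect_equal(sum(estimate_branch_lengths_jc(two, same)), 0)

  # consistency: error shrinks with sequence length
  truth <- simulate_birth_death_tree(20, 1, 0.5, seed = 15)
  rates <- draw_rates(truth, rate_model("strict", mu_true = 0.01),
                      seed = 1)
  b <- true_branch_lengths(truth, rates)
  tr <- truth$tree
  tr$blen <- b
  err <- vapply(c(500, 5000), function(s) {
    a <- simulate_jc_sequences(tr, b, s = s, seed = 17)
    bh <- estimate_branch_lengths_jc(tr, a)
    ok <- b > 1e-4
    stats::median(abs(bh[ok] - b[ok]) / b[ok])
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.2)
})

test_that("identical-tip collapse", {
  tr <- toy_tree()
  aln <- matrix(c("A", "A", "C"), 3, 50,
                dimnames = list(c("A", "B", "C"), NULL))
  # A and B identical -> B dropped, 2 leaves remain
  red <- collapse_identical_tips(tr, aln)
  expect_equal(red$tree$n_leaf, 2L)
  expect_setequal(rownames(red$aln), c("A", "C"))
})

test_that("end-to-end replicate: exactness and reproducibility", {
  rep0 <- make_phylodynamics_replicate(
    n = 12, model = rate_model("strict", mu_true = 0.01),
    noise = noise_model("none"), seed = 71)
  d <- date_tree(rep0$tree, rep0$cal,
                 opts = solve_options(n_starts = 2, seed = 1))
  h <- tree_height(rep0$truth)
  expect_lt(max(abs(d$t - rep0$truth$t)), 1e-6 * h)
  expect_equal(d$mu, 0.01, tolerance = 1e-6)

  r1 <- make_phylodynamics_replicate(n = 10, seed = 80)
  r2 <- make_phylodynamics_replicate(n = 10, seed = 80)
  expect_identical(r1$bhat, r2$bhat)
  expect_identical(r1$truth$t, r2$truth$t)
})
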