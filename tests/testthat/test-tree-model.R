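test_that("newick parsing assigns the indexing convention", {
  tr <- toy_tree()
  expect_s3_class(tr, "rooted_tree")
  expect_equal(tr$n_leaf, 3L)
  expect_equal(tr$n_edge, 4L)
  expect_true(is.na(tr$parent[1]))              # root = id 0
  # three-block order: all leaf ids exceed all internal ids
  expect_true(min(leaf_ids(tr)) > max(internal_ids(tr)))
  # binary case: leaves exactly n-1 .. 2n-2
  expect_equal(leaf_ids(tr), 2:4)
  expect_equal(tr$label[leaf_ids(tr) + 1L], c("A", "B", "C"))
  expect_equal(tr$blen, c(0.01, 0.01, 0.02, 0.02))
})

test_that("parser error contract", {
  expect_error(parse_newick("(A:1);"), "fewer than 2 leaves")
  expect_error(parse_newick("((A:1,B:2:0.5);"), "offset")
  expect_error(parse_newick("(A:1,B);"), "missing branch length.*B")
  expect_warning(tr <- parse_newick("(A:1,B:-0.5);"), "clamped")
  expect_equal(tr$blen[node_by_label(tr, "B")], 0)
})

test_that("quoted labels and comments are handled", {
  tr <- parse_newick("('sp one':1,[note]B:2)root;")
  expect_true("sp one" %in% tr$label)
  expect_equal(tr$label[1], "root")
  rt <- parse_newick(write_newick(tr))
  expect_setequal(rt$label, tr$label)
})

test_that("write/parse round-trip preserves topology, labels, lengths", {
  for (seed in 1:100) {
    n <- sample(3:25, 1)
    tr <- random_tree(n, seed)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(tr2$label, tr$label)
    expect_equal(tr2$parent, tr$parent)
    expect_equal(tr2$blen, tr$blen, tolerance = 1e-10)
  }
})

test_that("write_newick emits the expected string and validates input", {
  tr <- toy_tree()
  expect_equal(write_newick(tr, lengths = c(1, 1, 2, 2)),
               "((A:1,B:2):1,C:2);")
  expect_error(write_newick(tr, lengths = c(1, 1, 2, -2)), "negative")
  expect_error(write_newick(tr, lengths = c(1, 2)), "per edge")
  ann <- c("", "", "[&date=2]", "", "")
  expect_match(write_newick(tr, node_annotations = ann),
               "A[&date=2]:0.01", fixed = TRUE)
})

test_that("root_to_node_distance matches hand values and a path oracle", {
  tr <- toy_tree()
  expect_equal(root_to_node_distance(tr, node_by_label(tr, "B")), 0.03)
  expect_equal(root_to_node_distance(tr, 0L), 0)
  expect_error(root_to_node_distance(tr, 99L), "invalid node")
  for (seed in 1:20) {
    t2 <- random_tree(sample(4:20, 1), seed + 500)
    for (lf in sample(leaf_ids(t2), 3))
      expect_equal(root_to_node_distance(t2, lf),
                   walk_root_path_sum(t2, lf))
    # depth difference along each edge equals its length
    d <- node_depths(t2)
    for (e in seq_len(t2$n_edge))
      expect_equal(d[e + 1L] - d[t2$parent[e + 1L] + 1L], t2$blen[e])
  }
})

test_that("mrca matches hand cases and a brute-force oracle", {
  tr <- toy_tree()
  u <- setdiff(internal_ids(tr), 0L)
  expect_equal(mrca_node(tr, node_by_label(tr, c("A", "B"))), u)
  expect_equal(mrca_node(tr, node_by_label(tr, c("A", "C"))), 0L)
  expect_error(mrca_node(tr, integer(0)), "empty")
  for (seed in 1:100) {
    t2 <- random_tree(sample(4:15, 1), seed + 900)
    ids <- sample(seq_len(t2$n_node) - 1L, sample(2:4, 1))
    expect_equal(mrca_node(t2, ids), brute_mrca(t2, ids))
  }
})

test_that("tree height", {
  tr <- toy_tree()
  expect_equal(tree_height(dated_tree(tr, c(0, 1, 2, 3, 2))), 3)
  expect_equal(tree_height(dated_tree(tr, rep(5, 5))), 0)
  # equals max over leaves of summed tau along the root path
  d <- dated_tree(tr, c(0, 1.2, 2, 3.5, 2.2))
  paths <- vapply(leaf_ids(tr), function(lf)
    walk_root_path_sum(tr, lf, d$tau), 0)
  expect_equal(tree_height(d), max(paths))
})

test_that("phylo interconversion is faithful", {
  for (seed in 1:10) {
    tr <- random_tree(sample(4:20, 1), seed + 40)
    phy <- as_phylo(tr)
    back <- from_phylo(phy)
    expect_equal(back$parent, tr$parent)
    expect_equal(back$blen, tr$blen)
  }
})

test_that("prune_tree keeps structure, lengths and carried values", {
  truth <- simulate_birth_death_tree(12, 1, 0.4, seed = 5)
  tr <- truth$tree
  keep <- sort(sample(leaf_ids(tr), 6))
  pr <- prune_tree(tr, keep, values = truth$t)
  expect_equal(pr$tree$n_leaf, 6L)
  expect_setequal(pr$tree$label[leaf_ids(pr$tree) + 1L],
                  tr$label[keep + 1L])
  # root-to-leaf path lengths are preserved relative to the new root
  new_root_old <- pr$old_id[1]
  for (lf_new in leaf_ids(pr$tree)) {
    old <- pr$old_id[lf_new + 1L]
    expect_equal(walk_root_path_sum(pr$tree, lf_new),
                 walk_root_path_sum(tr, old) -
                   walk_root_path_sum(tr, new_root_old))
  }
  # carried node times survive pruning
  expect_equal(pr$values, truth$t[pr$old_id + 1L])
})
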