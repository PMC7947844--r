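## Desk-scale re-simulation of the autocorrelated-rate study: 50-taxon
## ultrametric birth-death trees, log-rate Brownian clock (root rate 0.01,
## increment variance 0.3 per unit duration), JC sequences of 1000 bases,
## fixed-topology JC-ML branch lengths, ~10% of internal nodes drawn as
## calibration points. Shared by the test suite and the acceptance script
## so both report the same computation.

#' Autocorrelated-rate simulation study
#'
#' For each replicate, simulates the data set, then for each of `n_draws`
#' random calibration draws dates the tree with wLogDate and with LF and
#' records the height-normalized RMSE of the uncalibrated internal node
#' ages. Additionally infers a unit time tree per replicate (identical
#' sequences collapsed, root calibrated at 0 and all tips at 1, wLogDate)
#' and records per-internal-node relative errors against the normalized
#' true tree.
#'
#' @param n_rep number of replicates (default 10)
#' @param n_taxa taxa per replicate (default 50)
#' @param n_draws calibration draws per replicate (default 5)
#' @param s sites (default 1000)
#' @param cal_frac fraction of internal nodes used as calibrations
#'   (default 0.1)
#' @param n_starts solver starts (default 10)
#' @param weights wlogdate weight variant ("sqrt" or "linear")
#' @param birth,death birth-death simulation rates
#' @param seed master seed
#' @param max_rmse tests in which any objective yields a normalized RMSE
#'   above this value (default 1: the dating error exceeds the whole tree
#'   height, i.e. the run failed outright) are discarded from every
#'   objective's average, mirroring the published protocol of dropping
#'   tests with extremely erroneous time trees
#' @return list(rmse = data.frame(rep, draw, scheme, rmse), with failed
#'   tests removed; n_discarded; unit = data.frame(rep, rel_err))
#' @export
autocorrelated_study <- function(n_rep = 10, n_taxa = 50, n_draws = 5,
                                 s = 1000, cal_frac = 0.1, n_starts = 10,
                                 birth = 1, death = 0.5, seed = 1,
                                 weights = "sqrt", max_rmse = 1) {
  rmse <- list(); unit <- list()
  for (r in seq_len(n_rep)) {
    sd_r <- .child_seed(seed, 17 * r)
    truth <- simulate_birth_death_tree(n_taxa, birth, death,
                                       sampling = "ultrametric",
                                       seed = .child_seed(sd_r, 1))
    rates <- draw_rates(truth, rate_model("autocorrelated"),
                        seed = .child_seed(sd_r, 2))
    b <- true_branch_lengths(truth, rates)
    tree <- truth$tree
    tree$blen <- b
    aln <- simulate_jc_sequences(tree, b, s = s,
                                 seed = .child_seed(sd_r, 3))
    bhat <- estimate_branch_lengths_jc(tree, aln)
    est_tree <- tree
    est_tree$blen <- bhat
    height <- tree_height(truth)
    internal <- internal_ids(tree)
    n_cal <- max(2L, round(cal_frac * length(internal)))
    for (d in seq_len(n_draws)) {
      cal_nodes <- .with_seed(.child_seed(sd_r, 100 + d), {
        for (try in 1:50) {
          cand <- sort(sample(internal, n_cal))
          if (length(unique(truth$t[.id(cand)])) >= 2L) break
        }
        cand
      })
      ## tips are extant and contemporaneous: their common sampling time
      ## (the present) is part of the date file, alongside the internal
      ## calibration points
      lv_all <- leaf_ids(tree)
      cal <- calibration_set(c(cal_nodes, lv_all),
                             c(truth$t[.id(cal_nodes)],
                               truth$t[.id(lv_all)]))
      free <- setdiff(internal, cal_nodes)
      for (scheme in c("wlogdate", "lf")) {
        dd <- date_tree(est_tree, cal, objective = scheme, s = s,
                        weights = weights,
                        opts = solve_options(n_starts = n_starts,
                                             seed = .child_seed(sd_r, 200 + d)))
        rmse[[length(rmse) + 1L]] <- data.frame(
          rep = r, draw = d, scheme = scheme,
          rmse = normalized_rmse(truth$t[.id(free)], dd$t[.id(free)],
                                 height))
      }
    }
    ## unit time tree: dedup identical sequences, root at 0, tips at 1
    red <- collapse_identical_tips(tree, aln, values = truth$t)
    t_norm <- (red$values - red$values[1]) /
      (max(red$values[.id(leaf_ids(red$tree))]) - red$values[1])
    red_tree <- red$tree
    red_tree$blen <- estimate_branch_lengths_jc(red_tree, red$aln)
    lv <- leaf_ids(red_tree)
    cal_u <- calibration_set(c(0L, lv), c(0, rep(1, length(lv))))
    du <- date_tree(red_tree, cal_u, objective = "wlogdate", s = s,
                    weights = weights,
                    opts = solve_options(n_starts = n_starts,
                                         seed = .child_seed(sd_r, 300)))
    keep <- setdiff(internal_ids(red_tree), 0L)
    keep <- keep[t_norm[.id(keep)] > 1e-9]
    err <- relative_node_error(t_norm[.id(keep)], du$t[.id(keep)])
    unit[[length(unit) + 1L]] <- data.frame(rep = r,
                                            rel_err = err$per_node)
  }
  rmse <- do.call(rbind, rmse)
  key <- paste(rmse$rep, rmse$draw)
  bad <- unique(key[rmse$rmse > max_rmse])
  list(rmse = rmse[!(key %in% bad), , drop = FALSE],
       n_discarded = length(bad),
       unit = do.call(rbind, unit))
}
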