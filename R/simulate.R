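## Simulation toolkit: birth-death time trees (ultrametric or with periodic
## heterochronous sampling), relaxed-clock rate models, branch-length noise
## models, Jukes-Cantor sequence simulation, and fixed-topology JC branch
## length estimation. Everything is seeded and reproducible.

#' Rate model description
#' @param kind "strict", "lognormal", "gamma", "exponential" or
#'   "autocorrelated"
#' @param mu_true global rate the i.i.d. multipliers are centered on
#'   (default 0.006 substitutions/site/time, the phylodynamics setting)
#' @param sd_lognormal sd of the LogNormal multiplier (mean 1; default 0.4)
#' @param shape_gamma shape = rate of the Gamma multiplier (default 6.05)
#' @param init_rate root rate of the autocorrelated model (default 0.01)
#' @param autocorr variance of the log-rate Brownian increment per unit
#'   branch duration (default 0.3)
#' @return list of class `rate_model`
#' @export
rate_model <- function(kind = c("strict", "lognormal", "gamma",
                                "exponential", "autocorrelated"),
                       mu_true = 0.006, sd_lognormal = 0.4,
                       shape_gamma = 6.05, init_rate = 0.01,
                       autocorr = 0.3) {
  structure(list(kind = match.arg(kind), mu_true = mu_true,
                 sd_lognormal = sd_lognormal, shape_gamma = shape_gamma,
                 init_rate = init_rate, autocorr = autocorr),
            class = "rate_model")
}

#' Branch-length noise model
#' @param kind "none", "poisson" (bhat = Poisson(s b)/s), "gaussian"
#'   (bhat = max(0, Normal(b, sqrt(b/s)))) or "jc_ml" (simulate JC
#'   sequences and re-estimate by ML)
#' @param s sequence length in sites
#' @return list of class `noise_model`
#' @export
noise_model <- function(kind = c("none", "poisson", "gaussian", "jc_ml"),
                        s = 1000) {
  if (s < 1) stop("s must be >= 1")
  structure(list(kind = match.arg(kind), s = s), class = "noise_model")
}

#' Simulate a birth-death time tree
#'
#' Forward (Gillespie) simulation from two root lineages. In "ultrametric"
#' mode the process stops when n extant lineages are first reached and all
#' of them are sampled at that moment. In "periodic" mode, once the extant
#' count reaches the per-epoch sample size, `n/epochs` random extant
#' lineages are sampled (removed) at regular time intervals until n tips
#' are collected, giving heterochronous tips. The returned tree is the
#' genealogy of the sampled tips only.
#'
#' @param n number of sampled tips (>= 3)
#' @param birth per-lineage birth rate (> death)
#' @param death per-lineage death rate (>= 0)
#' @param sampling "ultrametric" or "periodic"
#' @param epochs number of sampling epochs in periodic mode (default 5)
#' @param epoch_spacing time between epochs (default 0.5 / (birth - death))
#' @param seed optional RNG seed
#' @param max_retry attempts before giving up on an extinct process
#' @return a `dated_tree` (times increase toward the present; root at 0)
#' @export
simulate_birth_death_tree <- function(n, birth = 1, death = 0.5,
                                      sampling = c("ultrametric",
                                                   "periodic"),
                                      epochs = 5,
                                      epoch_spacing = 0.5 / (birth - death),
                                      seed = NULL, max_retry = 100) {
  sampling <- match.arg(sampling)
  if (n < 3) stop("n must be >= 3")
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  .with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      out <- .bd_once(n, birth, death, sampling, epochs, epoch_spacing)
      if (!is.null(out)) return(out)
    }
    stop("birth-death process went extinct in ", max_retry, " attempts")
  })
}

.bd_once <- function(n, birth, death, sampling, epochs, epoch_spacing) {
  per_epoch <- ceiling(n / epochs)
  ## node records (growable): parent key, birth time of the node's edge end
  parent <- c(NA_integer_, 1L, 1L)
  btime <- c(0, NA_real_, NA_real_)   # time the node terminates (set later)
  start <- c(0, 0, 0)                 # time the node's edge began
  active <- c(2L, 3L)
  sampled <- integer(0)
  t_now <- 0
  next_epoch <- Inf
  sampling_on <- FALSE
  nmax_nodes <- 20000L
  while (TRUE) {
    L <- length(active)
    if (L == 0L) return(NULL)                       # extinction
    if (sampling == "ultrametric" && L >= n) {
      take <- active
      btime[take] <- t_now
      sampled <- take
      break
    }
    if (sampling == "periodic" && !sampling_on && L >= 2L * per_epoch) {
      sampling_on <- TRUE
      next_epoch <- t_now
    }
    dt <- stats::rexp(1, (birth + death) * L)
    if (sampling == "periodic" && t_now + dt >= next_epoch) {
      t_now <- next_epoch
      m <- min(per_epoch, n - length(sampled), L - 1L)
      if (m >= 1L) {
        take <- sample(active, m)
        btime[take] <- t_now
        sampled <- c(sampled, take)
        active <- setdiff(active, take)
      }
      if (length(sampled) >= n) break
      next_epoch <- next_epoch + epoch_spacing
      next
    }
    t_now <- t_now + dt
    who <- active[sample.int(length(active), 1L)]
    if (stats::runif(1) < birth / (birth + death)) { # birth
      btime[who] <- t_now
      k <- length(parent)
      parent <- c(parent, who, who)
      start <- c(start, t_now, t_now)
      btime <- c(btime, NA_real_, NA_real_)
      active <- c(setdiff(active, who), k + 1L, k + 2L)
      if (length(parent) > nmax_nodes)
        stop("birth-death simulation exceeded ", nmax_nodes, " nodes")
    } else {                                        # death
      btime[who] <- t_now
      active <- setdiff(active, who)
    }
  }
  ## genealogy: durations as branch lengths, then prune to sampled tips
  blen_full <- btime - start
  lab <- character(length(parent))
  lab[sampled] <- paste0("t", seq_along(sampled))
  res <- .assemble_tree(parent, lab, blen_full)
  tree <- res$tree
  t_node <- btime[res$old_key]
  keep <- which(nzchar(tree$label)) - 1L
  keep <- keep[keep %in% leaf_ids(tree)]
  pr <- prune_tree(tree, keep, values = t_node)
  dated_tree(pr$tree, pr$values - pr$values[1])   # root at time 0
}

#' Draw per-edge substitution rates under a clock model
#'
#' i.i.d. models multiply `mu_true` by a mean-1 multiplier (LogNormal with
#' mean 1, sd `sd_lognormal`; Gamma with shape = rate = `shape_gamma`;
#' Exponential with rate 1). The autocorrelated model evolves log-rates by
#' Brownian motion along the tree: child log-rate ~ Normal(parent log-rate,
#' autocorr * branch duration), root rate `init_rate`; the edge rate is the
#' value at the edge's child end.
#'
#' @param dated a `dated_tree` (true time tree)
#' @param model a `rate_model`
#' @param seed optional RNG seed
#' @return numeric per-edge rates indexed by edge id
#' @export
draw_rates <- function(dated, model, seed = NULL) {
  stopifnot(inherits(dated, "dated_tree"), inherits(model, "rate_model"))
  tree <- dated$tree
  E <- tree$n_edge
  .with_seed(seed, switch(
    model$kind,
    strict = rep(model$mu_true, E),
    lognormal = {
      sdlog <- sqrt(log(1 + model$sd_lognormal^2))
      model$mu_true * stats::rlnorm(E, meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog)
    },
    gamma = model$mu_true * stats::rgamma(E, shape = model$shape_gamma,
                                          rate = model$shape_gamma),
    exponential = model$mu_true * stats::rexp(E, rate = 1),
    autocorrelated = {
      lograte <- numeric(tree$n_node)
      lograte[1] <- log(model$init_rate)
      for (id in tree$preorder) if (id > 0L) {
        p <- tree$parent[.id(id)]
        v <- model$autocorr * max(dated$tau[id], 0)
        ## -v/2 mean correction: the child's expected rate equals the
        ## parent's (the rate process is a martingale, not just log-rate)
        lograte[.id(id)] <- stats::rnorm(1, lograte[.id(p)] - v / 2,
                                         sqrt(v))
      }
      ## branch rate = average of the rates at the edge's two ends (the
      ## convention of autocorrelated-rate simulators)
      r <- exp(lograte)
      e <- seq_len(E)
      (r[.id(e)] + r[.id(tree$parent[.id(e)])]) / 2
    }))
}

#' True substitution-unit branch lengths b = rate * duration
#' @param dated a `dated_tree`
#' @param rates per-edge rates (from [draw_rates()])
#' @return per-edge expected substitutions per site
#' @export
true_branch_lengths <- function(dated, rates) {
  stopifnot(length(rates) == dated$tree$n_edge)
  rates * pmax(dated$tau, 0)
}

#' Add branch-length estimation noise
#' @param b true per-edge lengths (>= 0)
#' @param noise a `noise_model` of kind "none", "poisson" or "gaussian"
#' @param seed optional RNG seed
#' @return noisy per-edge lengths bhat >= 0
#' @export
add_branch_noise <- function(b, noise, seed = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(b < 0)) stop("negative true branch length")
  .with_seed(seed, switch(
    noise$kind,
    none = b,
    poisson = stats::rpois(length(b), noise$s * b) / noise$s,
    gaussian = pmax(0, stats::rnorm(length(b), b, sqrt(b / noise$s))),
    jc_ml = stop("jc_ml noise requires simulate_jc_sequences + ",
                 "estimate_branch_lengths_jc")))
}

## ---- Jukes-Cantor sequences ---------------------------------------------

.jc_p_change <- function(b) 0.75 * (1 - exp(-4 * b / 3))

#' Simulate sequences under the Jukes-Cantor model
#'
#' Root sequence uniform over A, C, G, T; each edge substitutes each site
#' independently with the exact JC transition probabilities for its
#' substitution-unit length.
#'
#' @param tree a `rooted_tree`
#' @param b per-edge substitution-unit lengths (default: tree's own)
#' @param s number of sites
#' @param seed optional RNG seed
#' @return character matrix (tips x sites) with leaf labels as rownames
#' @export
simulate_jc_sequences <- function(tree, b = NULL, s = 1000, seed = NULL) {
  .check_tree(tree)
  if (is.null(b)) b <- tree$blen
  if (any(b < 0)) stop("negative branch length")
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    seqs <- vector("list", tree$n_node)
    seqs[[1]] <- sample.int(4L, s, replace = TRUE)
    for (id in tree$preorder) if (id > 0L) {
      p <- seqs[[.id(tree$parent[.id(id)])]]
      pc <- .jc_p_change(b[id])
      x <- p
      hit <- stats::runif(s) < pc
      nh <- sum(hit)
      if (nh)   # a changed site moves to one of the three other states
        x[hit] <- ((p[hit] - 1L + sample.int(3L, nh, replace = TRUE)) %% 4L) + 1L
      seqs[[.id(id)]] <- x
    }
    lv <- leaf_ids(tree)
    out <- matrix("", length(lv), s)
    rownames(out) <- tree$label[.id(lv)]
    for (j in seq_along(lv)) out[j, ] <- bases[seqs[[.id(lv[j])]]]
    out
  })
}

#' Write an alignment matrix as FASTA
#' @param aln character matrix with taxon rownames
#' @param path output file
#' @return invisibly, the path
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

## canonical bipartition key of an edge: the leaf-label set on the side not
## containing the reference label
.split_key <- function(labels_side, all_labels, ref) {
  side <- if (ref %in% labels_side) setdiff(all_labels, labels_side)
  else labels_side
  paste(sort(side), collapse = "\r")
}

#' Fixed-topology ML branch lengths under Jukes-Cantor
#'
#' Estimates substitution-unit branch lengths on the given rooted topology
#' from an alignment, by maximum likelihood under JC (phangorn's pruning
#' likelihood with per-edge optimization on the unrooted topology). Under a
#' reversible model the two root-adjacent edges are identified only through
#' their sum; the merged estimate is split in proportion to the tree's own
#' branch lengths (`root_split = "proportional"`, the default, falling back
#' to an even split when they are absent or zero).
#'
#' @param tree a `rooted_tree` carrying the true topology
#' @param aln character matrix from [simulate_jc_sequences()] (rownames
#'   must match the leaf labels)
#' @param root_split "proportional" or "equal"
#' @return per-edge estimated lengths bhat, indexed like tree edges
#' @export
estimate_branch_lengths_jc <- function(tree, aln,
                                       root_split = c("proportional",
                                                      "equal")) {
  .check_tree(tree)
  root_split <- match.arg(root_split)
  labs <- tree$label[.id(leaf_ids(tree))]
  if (!all(labs %in% rownames(aln)))
    stop("alignment is missing sequences for some leaves")
  if (tree$n_leaf == 2L) {   # closed form: JC distance of the pair
    p <- mean(aln[labs[1], ] != aln[labs[2], ])
    d <- if (p >= 0.75) 5 else -0.75 * log(1 - 4 * p / 3)
    w <- tree$blen
    if (root_split == "equal" || sum(w) <= 0) w <- c(1, 1)
    return(d * w / sum(w))
  }
  phy <- as_phylo(tree)
  phy$node.label <- NULL
  uphy <- ape::unroot(phy)
  uphy$edge.length <- pmax(uphy$edge.length, 1e-6)
  dat <- phangorn::phyDat(aln[labs, , drop = FALSE], type = "DNA")
  fit <- phangorn::pml(uphy, dat)
  fit <- phangorn::optim.pml(fit, model = "JC", optEdge = TRUE,
                             control = phangorn::pml.control(
                               trace = 0, eps = 1e-8, maxit = 50))
  est <- fit$tree
  ## map estimated edges back to our edges via bipartitions
  ref <- labs[1]
  est_key <- character(nrow(est$edge)); est_len <- est$edge.length
  desc <- phangorn::Descendants(est, type = "tips")
  for (r in seq_len(nrow(est$edge))) {
    child <- est$edge[r, 2]
    tips <- if (child <= length(est$tip.label)) child else desc[[child]]
    est_key[r] <- .split_key(est$tip.label[tips], labs, ref)
  }
  bhat <- numeric(tree$n_edge)
  root_kids <- tree$children[[1]]
  merged <- length(root_kids) == 2L   # binary root: shared merged edge
  for (id in seq_len(tree$n_edge)) {
    tips_id <- intersect(.subtree_ids(tree, id), leaf_ids(tree))
    key <- .split_key(tree$label[.id(tips_id)], labs, ref)
    hit <- which(est_key == key)
    if (!length(hit))
      stop("could not match edge of node ", id, " in the estimated tree")
    bhat[id] <- est_len[hit[1]]
  }
  if (merged) {                       # split the merged root edge
    c1 <- root_kids[1]; c2 <- root_kids[2]
    Lm <- bhat[c1]                    # both children matched the same edge
    w <- tree$blen[c(c1, c2)]
    if (root_split == "equal" || sum(w) <= 0) w <- c(1, 1)
    bhat[c1] <- Lm * w[1] / sum(w)
    bhat[c2] <- Lm * w[2] / sum(w)
  }
  pmax(bhat, 0)
}

#' Collapse identical sequences to a single representative tip
#' @param tree a `rooted_tree`
#' @param aln character matrix of tip sequences
#' @param values optional per-node numeric vector carried through pruning
#' @return list(tree, aln, values, old_id) after dropping duplicate-sequence
#'   tips (first occurrence kept)
#' @export
collapse_identical_tips <- function(tree, aln, values = NULL) {
  .check_tree(tree)
  labs <- tree$label[.id(leaf_ids(tree))]
  seqkey <- apply(aln[labs, , drop = FALSE], 1, paste, collapse = "")
  keep_lab <- labs[!duplicated(seqkey)]
  if (length(keep_lab) < 2L) stop("fewer than 2 distinct sequences")
  keep <- leaf_ids(tree)[labs %in% keep_lab]
  pr <- prune_tree(tree, keep, values = values)
  list(tree = pr$tree, aln = aln[keep_lab, , drop = FALSE],
       values = pr$values, old_id = pr$old_id)
}

#' End-to-end phylodynamics replicate
#'
#' Simulates a birth-death time tree with periodic (heterochronous) tip
#' sampling, draws per-edge rates, forms true substitution-unit lengths,
#' applies the requested noise (direct noise or JC sequences + fixed-
#' topology ML re-estimation), and returns the leaf calibrations from the
#' true tip times.
#'
#' @param n tips (default 30 at desk scale)
#' @param model a `rate_model` (default LogNormal around mu = 0.006)
#' @param noise a `noise_model` (default gaussian, s = 1000)
#' @param birth,death birth-death rates
#' @param sampling "periodic" (default) or "ultrametric"
#' @param seed optional RNG seed
#' @return list(truth = true `dated_tree`, tree = `rooted_tree` with bhat
#'   as branch lengths, bhat, rates, cal = leaf `calibration_set`)
#' @export
make_phylodynamics_replicate <- function(n = 30,
                                         model = rate_model("lognormal"),
                                         noise = noise_model("gaussian"),
                                         birth = 1, death = 0.5,
                                         sampling = "periodic",
                                         seed = NULL) {
  truth <- simulate_birth_death_tree(n, birth, death, sampling = sampling,
                                     seed = .child_seed(seed, 1))
  rates <- draw_rates(truth, model, seed = .child_seed(seed, 2))
  b <- true_branch_lengths(truth, rates)
  tree <- truth$tree
  if (noise$kind == "jc_ml") {
    aln <- simulate_jc_sequences(tree, b, s = noise$s,
                                 seed = .child_seed(seed, 3))
    tree$blen <- b
    bhat <- estimate_branch_lengths_jc(tree, aln)
  } else {
    bhat <- add_branch_noise(b, noise, seed = .child_seed(seed, 3))
  }
  tree$blen <- bhat
  lv <- leaf_ids(tree)
  cal <- calibration_set(lv, truth$t[.id(lv)], tree$label[.id(lv)])
  list(truth = truth, tree = tree, bhat = bhat, rates = rates, cal = cal)
}
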