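## Node indexing convention used throughout:
##   - every node has an integer index ("id"); the root is always 0
##   - internal nodes occupy the low block 0..(n_internal-1), in preorder
##   - leaves occupy the high block n_internal..(n_node-1)
##   - for a binary tree with n leaves this yields internal ids 0..n-2 and
##     leaf ids n-1..2n-2
## Edges are identified with their child node: edge i = (parent(i), i) for
## every non-root id i in 1..n_edge, so a per-edge vector v has v[i] for
## node id i.

.id <- function(i) i + 1L  # id -> storage position

#' Construct a rooted tree from parent pointers
#'
#' Internal builder: takes node records keyed by arbitrary integer keys and
#' reindexes them into the package convention (root = 0, internal block,
#' leaf block; both in preorder).
#'
#' @param parent integer vector, parent key per node key (NA for root)
#' @param label character vector of node labels ("" if none)
#' @param blen numeric vector of branch lengths keyed like `parent`
#'   (value for the root is ignored)
#' @return list(tree = rooted_tree, old_key = integer vector mapping new id
#'   (position id+1) to the original key)
#' @keywords internal
#' @noRd
.assemble_tree <- function(parent, label, blen) {
  n <- length(parent)
  root_key <- which(is.na(parent))
  if (length(root_key) != 1L)
    stop("tree must have exactly one root, found ", length(root_key))
  kids <- vector("list", n)
  for (k in seq_len(n)) {
    p <- parent[k]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], k)
  }
  is_leaf <- lengths(kids) == 0L
  if (sum(is_leaf) < 2L) stop("tree has fewer than 2 leaves")
  if (is_leaf[root_key]) stop("root cannot be a leaf")
  ## iterative preorder over keys
  pre <- integer(n); stack <- root_key; top <- 1L; m <- 0L
  while (top > 0L) {
    k <- stack[top]; top <- top - 1L
    m <- m + 1L; pre[m] <- k
    ch <- kids[[k]]
    if (length(ch))
      for (c in rev(ch)) { top <- top + 1L; stack[top] <- c }
  }
  if (m != n) stop("tree contains nodes unreachable from the root")
  n_internal <- sum(!is_leaf)
  new_id <- integer(n)  # key -> new id
  ni <- 0L; nl <- n_internal
  for (k in pre) {
    if (is_leaf[k]) { new_id[k] <- nl; nl <- nl + 1L }
    else            { new_id[k] <- ni; ni <- ni + 1L }
  }
  ord <- order(new_id)           # keys sorted by new id
  par_new <- ifelse(is.na(parent[ord]), NA_integer_, new_id[parent[ord]])
  tree <- structure(list(
    n_leaf     = n - n_internal,
    n_internal = n_internal,
    n_node     = n,
    n_edge     = n - 1L,
    parent     = as.integer(par_new),
    children   = lapply(ord, function(k) new_id[kids[[k]]]),
    label      = as.character(label[ord]),
    blen       = as.numeric(blen[ord][-1L])
  ), class = "rooted_tree")
  tree$preorder <- .preorder_ids(tree)
  list(tree = tree, old_key = ord)
}

.preorder_ids <- function(tree) {
  n <- tree$n_node
  out <- integer(n); stack <- 0L; top <- 1L; m <- 0L
  while (top > 0L) {
    id <- stack[top]; top <- top - 1L
    m <- m + 1L; out[m] <- id
    ch <- tree$children[[.id(id)]]
    if (length(ch))
      for (c in rev(ch)) { top <- top + 1L; stack[top] <- c }
  }
  out
}

.is_leaf <- function(tree, id) id >= tree$n_internal

#' Leaf ids of a rooted tree
#' @param tree a `rooted_tree`
#' @return integer vector of leaf node ids
#' @export
leaf_ids <- function(tree) seq.int(tree$n_internal, tree$n_node - 1L)

#' Internal node ids of a rooted tree (root first)
#' @param tree a `rooted_tree`
#' @return integer vector of internal node ids
#' @export
internal_ids <- function(tree) seq.int(0L, tree$n_internal - 1L)

.check_tree <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  invisible(tree)
}

## ---- newick tokenizer/parser -------------------------------------------

.newick_tokens <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  toks <- vector("list", n); nt <- 0L
  i <- 1L
  push <- function(type, value, pos) {
    nt <<- nt + 1L
    toks[[nt]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    c0 <- ch[i]
    if (c0 %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (c0 == "[") {                      # comment: strip, allow nesting
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        if (ch[j] == "[") depth <- depth + 1L
        if (ch[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth > 0L)
        stop("newick parse error at offset ", i, ": unterminated comment")
      i <- j; next
    }
    if (c0 == "'") {                      # quoted label, '' escapes a quote
      j <- i + 1L; buf <- character(0)
      repeat {
        if (j > n)
          stop("newick parse error at offset ", i, ": unterminated quote")
        if (ch[j] == "'") {
          if (j < n && ch[j + 1L] == "'") { buf <- c(buf, "'"); j <- j + 2L }
          else { j <- j + 1L; break }
        } else { buf <- c(buf, ch[j]); j <- j + 1L }
      }
      push("label", paste(buf, collapse = ""), i)
      i <- j; next
    }
    if (c0 %in% c("(", ")", ",", ":", ";")) {
      push(c0, c0, i); i <- i + 1L; next
    }
    j <- i                                # bare token
    while (j <= n && !(ch[j] %in% c("(", ")", ",", ":", ";", "[", "'",
                                    " ", "\t", "\n", "\r")))
      j <- j + 1L
    push("label", paste(ch[i:(j - 1L)], collapse = ""), i)
    i <- j
  }
  toks[seq_len(nt)]
}

#' Parse a newick string into a rooted tree
#'
#' Accepts quoted labels and bracket comments (comments are stripped);
#' internal node labels are preserved. Branch lengths are required on every
#' non-root edge; negative input lengths are clamped to zero with a warning.
#' The node indexing convention is: root = 0, internal nodes 0..n_internal-1
#' in preorder, leaves n_internal..n_node-1.
#'
#' @param text a single newick string, terminated by ";"
#' @return an object of class `rooted_tree`
#' @examples
#' tr <- parse_newick("((A:0.01,B:0.02):0.01,C:0.02);")
#' tr$n_leaf
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .newick_tokens(text)
  if (!length(toks)) stop("newick parse error at offset 1: empty input")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(tk, what) {
    off <- if (is.null(tk)) nchar(text) + 1L else tk$pos
    stop("newick parse error at offset ", off, ": ", what)
  }
  parent <- integer(0); label <- character(0); blen <- numeric(0)
  has_len <- logical(0)
  new_node <- function(par) {
    parent[length(parent) + 1L] <<- par
    label[length(label) + 1L] <<- ""
    blen[length(blen) + 1L] <<- NA_real_
    has_len[length(has_len) + 1L] <<- FALSE
    length(parent)
  }
  parse_clade <- function(par) {
    me <- new_node(par)
    tk <- peek()
    if (!is.null(tk) && tk$type == "(") {
      take()
      repeat {
        parse_clade(me)
        tk <- peek()
        if (is.null(tk)) fail(tk, "expected ',' or ')'")
        if (tk$type == ",") { take(); next }
        if (tk$type == ")") { take(); break }
        fail(tk, paste0("expected ',' or ')', got '", tk$value, "'"))
      }
    }
    tk <- peek()
    if (!is.null(tk) && tk$type == "label") { label[me] <<- take()$value }
    tk <- peek()
    if (!is.null(tk) && tk$type == ":") {
      take()
      tk <- peek()
      if (is.null(tk) || tk$type != "label")
        fail(tk, "expected branch length after ':'")
      v <- suppressWarnings(as.numeric(tk$value))
      if (is.na(v)) fail(tk, paste0("invalid branch length '", tk$value, "'"))
      take()
      blen[me] <<- v; has_len[me] <<- TRUE
    }
    me
  }
  parse_clade(NA_integer_)
  tk <- peek()
  if (is.null(tk) || tk$type != ";") fail(tk, "expected ';'")
  take()
  if (!is.null(peek()))
    fail(peek(), "trailing characters after ';'")
  ## branch length checks (root edge length, if present, is ignored)
  is_root <- is.na(parent)
  miss <- which(!is_root & !has_len)
  if (length(miss)) {
    nm <- label[miss[1]]
    stop("missing branch length on non-root node ",
         if (nzchar(nm)) sQuote(nm) else paste0("#", miss[1]))
  }
  neg <- which(!is_root & blen < 0)
  if (length(neg)) {
    warning(length(neg), " negative branch length(s) clamped to 0")
    blen[neg] <- 0
  }
  blen[is_root] <- NA_real_
  .assemble_tree(parent, label, blen)$tree
}

#' Read a rooted tree from a newick file
#' @param path path to a newick file (first tree is read)
#' @return a `rooted_tree`
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_newick(txt)
}

.quote_label <- function(x) {
  bad <- grepl("[](),:;'[ \t]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Serialize a rooted tree to newick
#'
#' @param tree a `rooted_tree`
#' @param lengths per-edge numeric vector indexed by edge id (default: the
#'   tree's own branch lengths); all values must be non-negative
#' @param node_annotations optional character vector of per-node comment
#'   strings, indexed by position id+1; emitted verbatim after the label
#'   (use e.g. `"[&date=2001.5]"`)
#' @param digits significant digits for branch lengths
#' @return a newick string
#' @export
write_newick <- function(tree, lengths = NULL, node_annotations = NULL,
                         digits = 10) {
  .check_tree(tree)
  if (is.null(lengths)) lengths <- tree$blen
  if (length(lengths) != tree$n_edge)
    stop("lengths must have one entry per edge (", tree$n_edge, ")")
  if (any(lengths < 0, na.rm = TRUE))
    stop("negative branch length in output vector")
  if (!is.null(node_annotations) && length(node_annotations) != tree$n_node)
    stop("node_annotations must have one entry per node")
  lab <- .quote_label(tree$label)
  fmt <- function(id) {
    ch <- tree$children[[.id(id)]]
    core <- if (length(ch))
      paste0("(", paste(vapply(ch, fmt, ""), collapse = ","), ")",
             lab[.id(id)])
    else lab[.id(id)]
    if (!is.null(node_annotations) && nzchar(node_annotations[.id(id)]))
      core <- paste0(core, node_annotations[.id(id)])
    if (id > 0L)
      core <- paste0(core, ":", sprintf("%.*g", digits, lengths[id]))
    core
  }
  paste0(fmt(0L), ";")
}

## ---- path / depth utilities --------------------------------------------

#' Distance from the root to a node
#'
#' Sum of edge lengths along the path from the root to node `i`; zero for
#' the root itself.
#'
#' @param tree a `rooted_tree`
#' @param i node id
#' @param lengths per-edge vector (default: the tree's branch lengths)
#' @return a number
#' @export
root_to_node_distance <- function(tree, i, lengths = NULL) {
  .check_tree(tree)
  if (is.null(lengths)) lengths <- tree$blen
  if (length(i) != 1L || is.na(i) || i < 0L || i >= tree$n_node)
    stop("invalid node index: ", i)
  d <- 0
  while (i > 0L) { d <- d + lengths[i]; i <- tree$parent[.id(i)] }
  d
}

#' All node depths (distance from the root), vectorized
#' @param tree a `rooted_tree`
#' @param lengths per-edge vector (default: tree branch lengths)
#' @return numeric vector by storage position (id+1)
#' @export
node_depths <- function(tree, lengths = NULL) {
  .check_tree(tree)
  if (is.null(lengths)) lengths <- tree$blen
  d <- numeric(tree$n_node)
  for (id in tree$preorder) if (id > 0L)
    d[.id(id)] <- d[.id(tree$parent[.id(id)])] + lengths[id]
  d
}

.path_to_root <- function(tree, i) {
  out <- integer(0)
  while (!is.na(i)) { out <- c(out, i); i <- tree$parent[.id(i)] }
  out
}

#' Most recent common ancestor of a set of nodes
#' @param tree a `rooted_tree`
#' @param node_set integer vector of node ids (non-empty)
#' @return the id of the MRCA
#' @export
mrca_node <- function(tree, node_set) {
  .check_tree(tree)
  node_set <- unique(as.integer(node_set))
  if (!length(node_set)) stop("mrca of an empty node set")
  if (any(node_set < 0L | node_set >= tree$n_node))
    stop("invalid node index in set")
  common <- .path_to_root(tree, node_set[1])
  for (i in node_set[-1]) {
    while (!(i %in% common)) {
      i <- tree$parent[.id(i)]
      if (is.na(i)) stop("nodes share no ancestor (corrupt tree)")
    }
    common <- common[which(common == i):length(common)]
  }
  common[1]
}

## edge ids (child ids) on the path from ancestor `a` down to node `i`
.edges_down <- function(tree, a, i) {
  out <- integer(0)
  while (i != a) {
    out <- c(out, i)
    i <- tree$parent[.id(i)]
    if (is.na(i)) stop("node ", a, " is not an ancestor of the target")
  }
  out
}

## all node ids in the subtree rooted at `u` (including u)
.subtree_ids <- function(tree, u) {
  out <- integer(0); stack <- u
  while (length(stack)) {
    id <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, id)
    stack <- c(stack, tree$children[[.id(id)]])
  }
  out
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("Rooted tree:", x$n_leaf, "leaves,", x$n_internal, "internal nodes,",
      x$n_edge, "edges\n")
  lab <- x$label[.id(leaf_ids(x))]
  shown <- paste(utils::head(lab, 6), collapse = ", ")
  if (x$n_leaf > 6) shown <- paste0(shown, ", ...")
  cat("Leaf labels:", shown, "\n")
  invisible(x)
}

## ---- ape interop --------------------------------------------------------

#' Convert a rooted tree to an ape "phylo" object
#' @param tree a `rooted_tree`
#' @param lengths per-edge vector (default: tree branch lengths)
#' @return an object of class `phylo`
#' @export
as_phylo <- function(tree, lengths = NULL) {
  .check_tree(tree)
  if (is.null(lengths)) lengths <- tree$blen
  n <- tree$n_leaf
  ## ape: tips 1..n, internals n+1.. with root n+1; our internals are in
  ## preorder so internal id j -> n + j + 1 keeps root = n + 1
  map <- integer(tree$n_node)
  map[.id(internal_ids(tree))] <- n + internal_ids(tree) + 1L
  map[.id(leaf_ids(tree))] <- leaf_ids(tree) - tree$n_internal + 1L
  nonroot <- seq_len(tree$n_edge)
  edge <- cbind(map[.id(tree$parent[.id(nonroot)])], map[.id(nonroot)])
  tip_lab <- tree$label[.id(leaf_ids(tree))]
  empty <- !nzchar(tip_lab)
  tip_lab[empty] <- paste0("t", leaf_ids(tree)[empty])
  phy <- structure(list(edge = edge,
                        edge.length = as.numeric(lengths[nonroot]),
                        tip.label = tip_lab,
                        node.label = tree$label[.id(internal_ids(tree))],
                        Nnode = tree$n_internal),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape "phylo" object to a rooted tree
#' @param phy a rooted `phylo` with edge lengths
#' @return a `rooted_tree`
#' @export
from_phylo <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("phylo object must be rooted")
  if (is.null(phy$edge.length)) stop("phylo object has no edge lengths")
  n_all <- max(phy$edge)
  parent <- rep(NA_integer_, n_all)
  blen <- rep(NA_real_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  if (any(blen[!is.na(parent)] < 0)) {
    warning("negative branch length(s) clamped to 0")
    blen <- pmax(blen, 0)
  }
  lab <- character(n_all)
  lab[seq_along(phy$tip.label)] <- phy$tip.label
  if (!is.null(phy$node.label))
    lab[length(phy$tip.label) + seq_along(phy$node.label)] <- phy$node.label
  .assemble_tree(parent, lab, blen)$tree
}

## ---- pruning ------------------------------------------------------------

#' Restrict a tree to a subset of leaves
#'
#' Drops all leaves not in `keep`, suppresses resulting unifurcations
#' (summing branch lengths), and re-roots at the MRCA of the kept leaves.
#' Optional per-node values (e.g. node times) are carried across.
#'
#' @param tree a `rooted_tree`
#' @param keep integer vector of leaf ids to keep (>= 2)
#' @param values optional numeric vector by storage position (id+1)
#' @return list(tree, values (or NULL), old_id: for each new node, the id it
#'   had in the input tree)
#' @export
prune_tree <- function(tree, keep, values = NULL) {
  .check_tree(tree)
  keep <- unique(as.integer(keep))
  if (any(!(keep %in% leaf_ids(tree)))) stop("keep must contain leaf ids")
  if (length(keep) < 2L) stop("fewer than 2 leaves would remain")
  keep_node <- logical(tree$n_node)
  for (k in keep) keep_node[.id(.path_to_root(tree, k))] <- TRUE
  ## new root: MRCA of kept leaves
  new_root <- mrca_node(tree, keep)
  anc <- .path_to_root(tree, new_root)
  keep_node[.id(setdiff(anc, new_root))] <- FALSE
  ids <- which(keep_node) - 1L
  ## effective child counts within the kept set
  nkid <- integer(tree$n_node)
  for (id in ids) if (id != new_root) {
    p <- tree$parent[.id(id)]
    nkid[.id(p)] <- nkid[.id(p)] + 1L
  }
  retain <- vapply(ids, function(id)
    id == new_root || id %in% keep || nkid[.id(id)] >= 2L, TRUE)
  kept <- ids[retain]
  ## closest retained ancestor + accumulated branch length
  key <- match(kept, kept)  # identity; records keyed 1..m in `kept` order
  m <- length(kept)
  parent <- rep(NA_integer_, m); blen2 <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    id <- kept[j]
    if (id == new_root) next
    acc <- 0
    p <- id
    repeat {
      acc <- acc + tree$blen[p]
      p <- tree$parent[.id(p)]
      if (p %in% kept) break
    }
    parent[j] <- match(p, kept)
    blen2[j] <- acc
  }
  res <- .assemble_tree(parent, tree$label[.id(kept)], blen2)
  old_id <- kept[res$old_key]
  vals <- if (is.null(values)) NULL else values[.id(old_id)]
  list(tree = res$tree, values = vals, old_id = old_id)
}
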