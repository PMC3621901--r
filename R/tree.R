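# Computation trees: rooted-binary representation for pruning, node
# classification (down_0..down_3), scaler shortcut dispatch, traversal,
# NNI neighborhoods, and random/caterpillar topologies.
#
# User-facing trees are ape "phylo" objects; the evaluator works on an
# internal "cptree" with node ids 1..n_tip for tips and n_tip+1..2*n_tip-1
# for internal nodes (root = n_tip + 1), each non-root node carrying the
# length of the edge above it.

#' Read / write trees in newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that accept
#' either a file path or a newick string and validate the result.
#'
#' @param x A file path or a newick string (must end in `;`).
#' @return `read_newick()`: an [ape::phylo] object. `write_newick()`: the
#'   newick string (also written to `path` if given).
#' @export
read_newick <- function(x) {
  phy <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(phy)) stop("newick parse error (unbalanced parentheses?)")
  if (anyDuplicated(phy$tip.label)) stop("newick error: duplicate tip labels")
  phy
}

#' @param phy An [ape::phylo] object.
#' @param path Optional output file.
#' @rdname read_newick
#' @export
write_newick <- function(phy, path = NULL) {
  txt <- ape::write.tree(phy)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

# ---- internal cptree representation ---------------------------------------

# Convert an ape phylo to a rooted-binary computation tree. Unrooted input
# (basal multifurcation) is resolved with a zero-length edge; under the
# reversible model the likelihood is invariant to that rooting (pulley
# principle).
as_cptree <- function(phy) {
  if (inherits(phy, "cptree")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    phy <- ape::multi2di(phy, random = FALSE)
  if (!ape::is.binary(phy))
    stop("tree structure error: could not resolve to a binary tree")
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree structure error: need at least 2 tips")
  nnode <- 2L * n - 1L
  parent <- integer(nnode)
  elen <- numeric(nnode)
  kids <- vector("list", nnode)
  eln <- phy$edge.length
  if (is.null(eln)) eln <- rep(0, nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    parent[ch] <- p
    elen[ch] <- eln[e]
    kids[[p]] <- c(kids[[p]], ch)
  }
  child <- matrix(0L, 2L, nnode)
  for (v in (n + 1L):nnode) {
    if (length(kids[[v]]) != 2L)
      stop("tree structure error: internal node without exactly 2 children")
    child[, v] <- kids[[v]]
  }
  root <- n + 1L
  if (parent[root] != 0L) stop("tree structure error: unexpected root id")
  tr <- structure(
    list(n_tip = n, tip_label = phy$tip.label, parent = parent,
         child = child, elen = elen, root = root),
    class = "cptree")
  tr$postorder <- cptree_postorder(tr)
  tr
}

# Convert back to ape phylo.
as_phylo <- function(tr) {
  if (inherits(tr, "phylo")) return(tr)
  stopifnot(inherits(tr, "cptree"))
  n <- tr$n_tip
  nnode <- 2L * n - 1L
  nonroot <- setdiff(seq_len(nnode), tr$root)
  edge <- cbind(tr$parent[nonroot], nonroot)
  phy <- structure(
    list(edge = edge, tip.label = tr$tip_label, Nnode = n - 1L,
         edge.length = tr$elen[nonroot]),
    class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' @export
print.cptree <- function(x, ...) {
  cat("computation tree:", x$n_tip, "tips,", x$n_tip - 1L,
      "internal nodes (rooted binary)\n")
  invisible(x)
}

# Postorder over internal nodes (children before parents, root last).
cptree_postorder <- function(tr) {
  n <- tr$n_tip
  out <- integer(n - 1L)
  k <- 0L
  seen <- logical(2L * n - 1L)
  stack <- tr$root
  visit <- integer(0)
  # iterative DFS; reverse finish order gives postorder
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    if (seen[v]) stop("tree structure error: cycle detected")
    seen[v] <- TRUE
    if (v > n) stack <- c(stack, tr$child[, v])
  }
  ints <- visit[visit > n]
  rev(ints)
}

#' Postorder traversal of a tree
#'
#' Returns the internal nodes in an order where every node appears after
#' both of its children (root last) -- the evaluation order of the pruning
#' pass.
#'
#' @param tree An [ape::phylo] or internal computation tree.
#' @return Integer vector of internal node ids (computation-tree ids:
#'   tips are `1..n`, internal nodes `n+1..2n-1`, root `n+1`).
#' @export
postorder_nodes <- function(tree) {
  tr <- as_cptree(tree)
  tr$postorder
}

# ---- node classification and shortcut dispatch ----------------------------

#' Classify internal nodes by which children are terminal
#'
#' A down node (internal, non-root) is `down_x` with
#' `x = (left child terminal) + 2 * (right child terminal)`: `down_0` has
#' two internal children, `down_1` a terminal left child, `down_2` a
#' terminal right child, `down_3` two terminal children. The four classes
#' partition the `n - 2` down nodes of a rooted binary tree on `n` taxa.
#'
#' @param tree An [ape::phylo] or computation tree.
#' @param node Optional single internal node id; if omitted, all internal
#'   nodes (including the root, which is classified the same way but
#'   dispatched to the root variant) are returned.
#' @return Named integer vector of class indices `x` in `0..3` (names
#'   `"down_x"`), indexed by node id.
#' @export
classify_node <- function(tree, node = NULL) {
  tr <- as_cptree(tree)
  n <- tr$n_tip
  ids <- if (is.null(node)) tr$postorder else as.integer(node)
  if (any(ids <= n)) stop("classify_node: called on a leaf")
  x <- (tr$child[1L, ids] <= n) + 2L * (tr$child[2L, ids] <= n)
  setNames(as.integer(x), paste0("down_", x))
}

#' Scaler shortcut index
#'
#' Maps the two scaler flags of a node to the shortcut `T = 2 S + N`, where
#' `S` indicates an old scaler must be removed (`scalersSet`) and `N` that a
#' new scaler must be computed (`scalerNode`). `T` selects, together with the
#' down-node class, which of the sixteen fused kernel variants runs.
#'
#' @param S,N Flag values in `{0, 1}` (vectorized).
#' @return Integer shortcut index in `0..3`.
#' @examples
#' shortcut(0, 0)  # 0
#' shortcut(1, 1)  # 3
#' @export
shortcut <- function(S, N) {
  S <- as.integer(S); N <- as.integer(N)
  if (any(!S %in% 0:1) || any(!N %in% 0:1))
    stop("shortcut: S and N must be 0 or 1")
  2L * S + N
}

#' The sixteen down-node dispatch variants
#'
#' Every down node is handled by exactly one variant `down_x_T`, the
#' combination of its shape class `x` (which children are terminal) and the
#' scaler shortcut `T` from [shortcut()].
#'
#' @return A data frame with columns `x`, `T`, `S`, `N` and `id`
#'   (16 rows, ids `down_0_0` .. `down_3_3`).
#' @export
variant_table <- function() {
  g <- expand.grid(T = 0:3, x = 0:3)[, c("x", "T")]
  g$S <- g$T %/% 2L
  g$N <- g$T %% 2L
  g$id <- sprintf("down_%d_%d", g$x, g$T)
  rownames(g) <- NULL
  g
}

# ---- splits ---------------------------------------------------------------

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge induces a split of the taxon set; splits are returned
#' as canonical strings ("included" taxa, sorted label order, oriented so
#' the first label is excluded) so they can be compared across trees and
#' rootings.
#'
#' @param tree An [ape::phylo] or computation tree.
#' @param labels Optional full taxon label set fixing the orientation
#'   (defaults to the tree's own sorted labels).
#' @return Character vector of canonical split keys (may be empty).
#' @export
tree_splits <- function(tree, labels = NULL) {
  tr <- as_cptree(tree)
  if (is.null(labels)) labels <- sort(tr$tip_label)
  n <- tr$n_tip
  below <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) below[[i]] <- tr$tip_label[i]
  for (v in tr$postorder)
    below[[v]] <- c(below[[tr$child[1L, v]]], below[[tr$child[2L, v]]])
  keys <- character(0)
  for (v in tr$postorder) {
    if (v == tr$root) next
    inc <- labels %in% below[[v]]
    if (inc[1L]) inc <- !inc            # orient: first label excluded
    if (sum(inc) >= 2L && sum(!inc) >= 2L)
      keys <- c(keys, paste(labels[inc], collapse = "|"))
  }
  unique(keys)
}

# ---- NNI ------------------------------------------------------------------

# Internal (unrooted-sense) edges of a computation tree, identified by the
# child node id. The two edges at the root form one unrooted edge between
# the root's children; it is internal only when both children are internal,
# and is represented once, by the root's first child.
internal_edges <- function(tr) {
  tr <- as_cptree(tr)
  n <- tr$n_tip
  rc <- tr$child[, tr$root]
  out <- integer(0)
  for (v in tr$postorder) {
    if (v == tr$root) next
    if (tr$parent[v] == tr$root) {
      if (all(rc > n) && v == rc[1L]) out <- c(out, v)
    } else out <- c(out, v)
  }
  out
}

#' Nearest-neighbor-interchange neighborhoods
#'
#' Returns the two standard NNI rearrangements of an internal edge; branch
#' lengths stay attached to their subtrees.
#'
#' @param tree An [ape::phylo] or computation tree (at least 4 taxa).
#' @param edge Id of the internal node below the edge (see
#'   [postorder_nodes()] for the id scheme); if omitted, a list over all
#'   internal edges is returned.
#' @return A list of two `phylo` trees (or a list of such lists).
#' @export
nni_neighbors <- function(tree, edge = NULL) {
  tr <- as_cptree(tree)
  if (tr$n_tip < 4L) stop("nni_neighbors: need at least 4 taxa")
  if (is.null(edge)) {
    es <- internal_edges(tr)
    return(setNames(lapply(es, function(e) nni_neighbors(tr, e)),
                    paste0("edge_", es)))
  }
  edge <- as.integer(edge)
  if (edge <= tr$n_tip || edge == tr$root || !(edge %in% internal_edges(tr)))
    stop("nni_neighbors: not an internal edge")
  lapply(1:2, function(k) as_phylo(cptree_nni(tr, edge, k)))
}

# One NNI variant (k = 1 or 2) around the edge above internal node v.
cptree_nni <- function(tr, v, k) {
  p <- tr$parent[v]
  a <- tr$child[k, v]                   # subtree of v to swap
  if (p == tr$root) {
    # unrooted edge through the root: swap with a child of the sibling
    sib <- tr$child[, tr$root]
    sib <- sib[sib != v]
    w <- tr$child[1L, sib]              # fixed convention: sibling's left child
    tr <- swap_subtrees(tr, a, w)
  } else {
    sib <- tr$child[, p]
    w <- sib[sib != v]                  # v's sibling under p
    tr <- swap_subtrees(tr, a, w)
  }
  tr$postorder <- cptree_postorder(tr)
  tr
}

# Exchange the positions of two disjoint subtrees (branch lengths travel
# with their subtree root).
swap_subtrees <- function(tr, a, b) {
  pa <- tr$parent[a]; pb <- tr$parent[b]
  tr$child[, pa][tr$child[, pa] == a] <- b
  tr$child[, pb][tr$child[, pb] == b] <- a
  tr$parent[a] <- pb
  tr$parent[b] <- pa
  tr
}

# ---- tree generation ------------------------------------------------------

#' Random tree with uniform unrooted topology
#'
#' Builds a topology by stepwise random addition (each new taxon attaches to
#' a uniformly chosen edge), which draws uniformly from the labeled unrooted
#' binary topologies; branch lengths are i.i.d. from `branch_fn`.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param branch_fn Function `n -> n` positive branch lengths; default
#'   `rexp(n, rate = 10)` (mean 0.1 substitutions/site).
#' @param labels Optional taxon labels (default `t1..tn`).
#' @return A rooted-binary [ape::phylo] (rooting is arbitrary; the
#'   likelihood does not depend on it).
#' @export
random_tree <- function(n_taxa, branch_fn = function(n) rexp(n, rate = 10),
                        labels = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 3L) stop("random_tree: need at least 3 taxa")
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  # grow an unrooted tree as an edge list; tips 1..n, internals n+1..
  n <- n_taxa
  nextint <- n + 1L
  edges <- rbind(c(nextint, 1L), c(nextint, 2L), c(nextint, 3L))
  nextint <- nextint + 1L
  if (n > 3L) for (tip in 4:n) {
    e <- sample.int(nrow(edges), 1L)
    mid <- nextint; nextint <- nextint + 1L
    old <- edges[e, ]
    edges[e, ] <- c(old[1L], mid)
    edges <- rbind(edges, c(mid, old[2L]), c(mid, tip))
  }
  phy <- structure(
    list(edge = edges, tip.label = labels, Nnode = n - 2L,
         edge.length = rep(0, nrow(edges))),
    class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy <- ape::multi2di(phy, random = FALSE)   # root the basal trifurcation
  phy$edge.length <- branch_fn(nrow(phy$edge))
  phy
}

#' Caterpillar (ladder) tree
#'
#' Rooted binary comb: the root has a tip and an internal child, every
#' internal node below has a tip and an internal child, closing with a
#' cherry. This is the shape used by the transfer-accounting scenario.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param branch_length Common branch length (default 0.05).
#' @return An [ape::phylo].
#' @export
caterpillar_tree <- function(n_taxa, branch_length = 0.05) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 3L) stop("caterpillar_tree: need at least 3 taxa")
  nwk <- paste0("t", n_taxa)
  for (i in (n_taxa - 1L):1L)
    nwk <- sprintf("(t%d:%g,%s:%g)", i, branch_length, nwk, branch_length)
  # collapse: innermost pair is (t_{n-1}, t_n); outermost pairs with t1
  phy <- read_newick(paste0(nwk, ";"))
  phy
}
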