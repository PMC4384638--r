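## Rooted-tree utilities: traversal helpers, pruning, the phylogenetic
## variance-covariance matrix, Pagel's lambda transform, ultrametricity.

tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
}

# list indexed by node id; children of each internal node (integer(0) for tips)
children_list <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(n_node)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2L])
  }
  kids
}

# numeric vector indexed by child node id; NA for the root
edge_length_by_child <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  len <- rep(NA_real_, n_node)
  len[tree$edge[, 2L]] <- tree$edge.length
  len
}

# root-to-node path length for every node (root = 0)
node_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  if (length(tree$tip.label) == 1L) {
    d <- c(tree$edge.length[1L], 0)
    return(d)
  }
  kids <- children_list(tree)
  elen <- edge_length_by_child(tree)
  depth <- rep(NA_real_, n_node)
  root <- tree_root(tree)
  depth[root] <- 0
  stack <- root
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (ch in kids[[nd]]) {
      depth[ch] <- depth[nd] + elen[ch]
      stack <- c(stack, ch)
    }
  }
  depth
}

#' Restrict a tree to a subset of its leaves
#'
#' Drops all leaves outside `keep`, suppresses the unary internal nodes this
#' creates (summing their branch lengths), and re-roots at the most recent
#' common ancestor of the retained leaves. Any residual path above that new
#' root is discarded, so depths are measured from the new root; under a full
#' Brownian model with an intercept, downstream regression results are
#' unaffected by this normalization.
#'
#' @param tree A `"phylo"` tree.
#' @param keep Character vector of leaf labels to retain (non-empty subset).
#' @return The pruned `"phylo"` tree with exactly `keep` as its leaf set.
#' @export
#' @examples
#' prune_to_taxa(parse_newick("((A:1,B:1):1,C:2);"), c("A", "B"))
prune_to_taxa <- function(tree, keep) {
  validate_phylo_tree(tree)
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("'keep' must be a non-empty set of leaf labels")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("labels absent from tree: ", paste(missing, collapse = ", "))
  if (setequal(keep, tree$tip.label) && length(tree$tip.label) > 1L) {
    out <- tree
    out$root.edge <- NULL
    return(out)
  }

  n_tip <- length(tree$tip.label)
  if (n_tip == 1L) return(tree)

  kids <- children_list(tree)
  elen <- edge_length_by_child(tree)
  keep_tip <- which(tree$tip.label %in% keep)

  if (length(keep_tip) == 1L) {
    d <- node_depths(tree)[keep_tip]
    out <- list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = d,
                tip.label = tree$tip.label[keep_tip], Nnode = 1L)
    class(out) <- "phylo"
    return(out)
  }

  # rebuild as a nested structure containing only retained leaves,
  # summing branch lengths through suppressed unary nodes
  build <- function(node, pending_len) {
    if (node <= n_tip) {
      if (!(node %in% keep_tip)) return(NULL)
      return(list(children = list(), label = tree$tip.label[node],
                  length = pending_len, pos = NA_integer_))
    }
    sub <- list()
    for (ch in kids[[node]]) {
      b <- build(ch, elen[ch])
      if (!is.null(b)) sub[[length(sub) + 1L]] <- b
    }
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) {
      sub[[1L]]$length <- sub[[1L]]$length + pending_len
      return(sub[[1L]])
    }
    list(children = sub, label = "", length = pending_len, pos = NA_integer_)
  }

  nested <- build(tree_root(tree), NA_real_)
  nested$length <- NA_real_   # discard any path above the new root
  out <- nested_to_phylo(nested)
  out$root.edge <- NULL
  validate_phylo_tree(out)
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion on a rooted tree, the covariance of trait values at
#' two leaves is proportional to the branch length shared on their root-to-tip
#' paths, i.e. the depth of their most recent common ancestor; the variance at
#' a leaf is its root-to-leaf depth. This matrix defines the error structure
#' used by [pgls_fit()].
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @return An object of class `"phylo_vcv"`: a list with `taxa` (leaf labels,
#'   in tip order), `V` (the symmetric covariance matrix, dimnames = taxa) and
#'   `lambda` (`"untransformed"` until [lambda_transform()] is applied).
#' @export
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))$V
phylo_vcv <- function(tree) {
  validate_phylo_tree(tree)
  n_tip <- length(tree$tip.label)
  depth <- node_depths(tree)
  V <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n_tip)]
  if (n_tip > 1L) {
    kids <- children_list(tree)
    # leaves under each node
    leaves_under <- vector("list", n_tip + tree$Nnode)
    post <- postorder_nodes(tree)
    for (nd in post) {
      if (nd <= n_tip) leaves_under[[nd]] <- nd
      else leaves_under[[nd]] <- unlist(leaves_under[kids[[nd]]], use.names = FALSE)
    }
    for (nd in post) {
      if (nd <= n_tip) next
      ch <- kids[[nd]]
      if (length(ch) < 2L) next
      for (a in seq_len(length(ch) - 1L)) {
        for (b in seq((a + 1L), length(ch))) {
          la <- leaves_under[[ch[a]]]
          lb <- leaves_under[[ch[b]]]
          V[la, lb] <- depth[nd]
          V[lb, la] <- depth[nd]
        }
      }
    }
  }
  structure(list(taxa = tree$tip.label, V = V, lambda = "untransformed"),
            class = "phylo_vcv")
}

# node ids in postorder (children before parents); iterative, so deep
# pectinate trees do not overflow the call stack
postorder_nodes <- function(tree) {
  kids <- children_list(tree)
  s <- tree_root(tree)
  pre <- integer(0)
  while (length(s)) {
    nd <- s[[length(s)]]
    s <- s[-length(s)]
    pre <- c(pre, nd)
    s <- c(s, kids[[nd]])
  }
  rev(pre)
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat(sprintf("Phylogenetic covariance over %d taxa (lambda: %s)\n",
              length(x$taxa), as.character(x$lambda)))
  print(x$V, ...)
  invisible(x)
}

#' @export
as.matrix.phylo_vcv <- function(x, ...) x$V

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies every off-diagonal entry by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` keeps the full Brownian structure; `lambda = 0`
#' removes all phylogenetic covariance (species become independent).
#'
#' @param V A `"phylo_vcv"` object that has not already been transformed.
#' @param lambda A number in `[0, 1]`.
#' @return A `"phylo_vcv"` with `lambda` recorded; positive semi-definiteness
#'   is preserved for all `lambda` in `[0, 1]`.
#' @export
lambda_transform <- function(V, lambda) {
  stopifnot(inherits(V, "phylo_vcv"))
  if (!identical(V$lambda, "untransformed"))
    stop("covariance already lambda-transformed (lambda = ", V$lambda, ")")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single number in [0, 1]")
  M <- V$V * lambda
  diag(M) <- diag(V$V)
  structure(list(taxa = V$taxa, V = M, lambda = lambda), class = "phylo_vcv")
}

#' Is a tree ultrametric?
#'
#' @param tree A `"phylo"` tree.
#' @param rel_tol Relative tolerance on root-to-leaf depths, as a fraction of
#'   the maximum depth.
#' @return `TRUE` iff all leaves are equidistant from the root within
#'   `rel_tol`.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylo_tree(tree)
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  if (length(d) == 1L) return(TRUE)
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (max(d) - min(d)) <= rel_tol * mx
}

#' Deterministically resolve polytomies
#'
#' Contrast computation needs a fully bifurcating tree. Multifurcations are
#' resolved into a ladder of zero-length internal branches, combining children
#' in the order of the smallest leaf label in each child subtree, so the
#' resolution is reproducible and leaves the covariance matrix unchanged.
#'
#' @param tree A `"phylo"` tree.
#' @return A binary `"phylo"` tree with the same leaf depths and covariance.
#' @export
resolve_polytomies <- function(tree) {
  validate_phylo_tree(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip <= 2L) return(tree)
  kids <- children_list(tree)
  elen <- edge_length_by_child(tree)

  min_label <- function(nested) {
    if (length(nested$children) == 0L) return(nested$label)
    min(vapply(nested$children, min_label, character(1L)))
  }
  rec <- function(node, len) {
    if (node <= n_tip)
      return(list(children = list(), label = tree$tip.label[node],
                  length = len, pos = NA_integer_))
    sub <- lapply(kids[[node]], function(ch) rec(ch, elen[ch]))
    ord <- order(vapply(sub, min_label, character(1L)))
    sub <- sub[ord]
    while (length(sub) > 2L) {
      merged <- list(children = sub[1:2], label = "", length = 0,
                     pos = NA_integer_)
      sub <- c(list(merged), sub[-(1:2)])
    }
    list(children = sub, label = "", length = len, pos = NA_integer_)
  }
  nested <- rec(tree_root(tree), NA_real_)
  out <- nested_to_phylo(nested)
  validate_phylo_tree(out)
  out
}
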