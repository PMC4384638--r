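# Brute-force oracles, independent of the package's own code paths.

# parent lookup for every node
parents_of <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, n_node)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# root-to-node depth by walking the parent chain (no shared code with
# phylo_vcv's postorder computation)
bf_depth <- function(tree, node) {
  par <- parents_of(tree)
  len <- rep(NA_real_, length(par))
  len[tree$edge[, 2L]] <- tree$edge.length
  d <- 0
  while (!is.na(par[node])) {
    d <- d + len[node]
    node <- par[node]
  }
  d
}

# ancestor set of a node (including itself)
bf_ancestors <- function(tree, node) {
  par <- parents_of(tree)
  anc <- node
  while (!is.na(par[node])) {
    node <- par[node]
    anc <- c(anc, node)
  }
  anc
}

# vcv by brute force: shared root-to-MRCA path length over all leaf pairs
bf_vcv <- function(tree) {
  n <- length(tree$tip.label)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    V[i, i] <- bf_depth(tree, i)
    if (i < n) for (j in seq((i + 1L), n)) {
      # deepest common ancestor by explicit path intersection
      common <- intersect(bf_ancestors(tree, i), bf_ancestors(tree, j))
      depths <- vapply(common, function(nd) bf_depth(tree, nd), numeric(1))
      V[i, j] <- V[j, i] <- max(depths)
    }
  }
  V
}

# GLS by explicit inversion of the covariance matrix (no factorizations)
bf_gls <- function(y, X, M, df) {
  Mi <- solve(M)
  beta <- solve(t(X) %*% Mi %*% X, t(X) %*% Mi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Mi %*% r) / df
  covb <- s2 * solve(t(X) %*% Mi %*% X)
  list(beta = as.numeric(beta), se = sqrt(diag(covb)),
       t = as.numeric(beta) / sqrt(diag(covb)))
}

# canonical Newick (children sorted by smallest leaf label, lengths rounded)
# for isomorphism checks
canonical_newick <- function(tree, digits = 9) {
  n_tip <- length(tree$tip.label)
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_along(kids)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  len <- rep(NA_real_, length(kids))
  len[tree$edge[, 2L]] <- tree$edge.length
  rec <- function(nd) {
    if (nd <= n_tip)
      return(list(lab = tree$tip.label[nd],
                  str = paste0(tree$tip.label[nd], ":",
                               signif(len[nd], digits))))
    sub <- lapply(kids[[nd]], rec)
    sub <- sub[order(vapply(sub, function(s) s$lab, character(1)))]
    list(lab = sub[[1]]$lab,
         str = paste0("(", paste(vapply(sub, function(s) s$str, character(1)),
                                 collapse = ","), ")",
                      if (!is.na(len[nd])) paste0(":", signif(len[nd], digits))
                      else ""))
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  paste0(rec(root)$str, ";")
}

# small random dataset on a random Yule tree
random_bm_pair <- function(n, seed, lambda = 1, rho = 0) {
  tr <- simulate_yule_tree(n, 1, seed = seed)
  R <- matrix(c(1, rho, rho, 1), 2, 2)
  X <- simulate_bm_traits(tr, R, lambda = lambda, seed = seed + 1000L)
  list(tree = tr,
       x = stats::setNames(X[[1]], rownames(X)),
       y = stats::setNames(X[[2]], rownames(X)))
}
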