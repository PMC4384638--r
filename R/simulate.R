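## Synthetic trees and traits with known ground truth: a Yule tree
## simulator, correlated Brownian-motion traits with exact Pagel's lambda,
## and a null-calibration battery. Every generator is a pure function of its
## arguments plus a mandatory seed.

#' Simulate a Yule (pure-birth) tree
#'
#' Starts from the root split (two lineages) and adds speciation events with
#' exponential waiting times of rate `k * birth_rate` while `k` lineages are
#' alive, splitting a uniformly chosen lineage, until `n_taxa` tips exist;
#' one final exponential epoch then runs to the present, so the tree is
#' ultrametric with expected depth `sum_{k=2..n} 1 / (k * birth_rate)`.
#'
#' @param n_taxa Number of tips (`>= 2`).
#' @param birth_rate Speciation rate (`> 0`), per unit branch length.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return An ultrametric `"phylo"` tree with tips `t1 ... tn` (numbered in
#'   order of appearance).
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed) {
  if (!is.numeric(n_taxa) || n_taxa < 2L || n_taxa != round(n_taxa))
    stop("'n_taxa' must be an integer >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("'birth_rate' must be > 0")
  if (missing(seed)) stop("'seed' is mandatory")
  n_taxa <- as.integer(n_taxa)

  withr::with_seed(seed, {
    # temp ids: 1 = root; lineages are open branches (parent id + birth time)
    next_id <- 1L
    edges_p <- integer(0); edges_c <- integer(0); edges_len <- numeric(0)
    is_tip <- logical(0)
    t_now <- 0
    lineage_parent <- c(1L, 1L)
    lineage_birth <- c(0, 0)
    while (length(lineage_parent) < n_taxa) {
      k <- length(lineage_parent)
      t_now <- t_now + stats::rexp(1L, rate = k * birth_rate)
      j <- sample.int(k, 1L)
      # lineage j speciates: becomes an internal node
      next_id <- next_id + 1L
      edges_p <- c(edges_p, lineage_parent[j])
      edges_c <- c(edges_c, next_id)
      edges_len <- c(edges_len, t_now - lineage_birth[j])
      is_tip <- c(is_tip, FALSE)
      lineage_parent <- c(lineage_parent[-j], next_id, next_id)
      lineage_birth <- c(lineage_birth[-j], t_now, t_now)
    }
    t_end <- t_now + stats::rexp(1L, rate = n_taxa * birth_rate)
    tip_ids <- integer(n_taxa)
    for (j in seq_len(n_taxa)) {
      next_id <- next_id + 1L
      edges_p <- c(edges_p, lineage_parent[j])
      edges_c <- c(edges_c, next_id)
      edges_len <- c(edges_len, t_end - lineage_birth[j])
      is_tip <- c(is_tip, TRUE)
      tip_ids[j] <- next_id
    }
    # renumber: tips 1..n in order of appearance, internals n+1.. (root first)
    internal_ids <- c(1L, edges_c[!is_tip])
    new_id <- integer(next_id)
    new_id[tip_ids] <- seq_len(n_taxa)
    new_id[internal_ids] <- n_taxa + seq_along(internal_ids)
    tree <- list(edge = cbind(new_id[edges_p], new_id[edges_c]),
                 edge.length = edges_len,
                 tip.label = paste0("t", seq_len(n_taxa)),
                 Nnode = length(internal_ids))
    dimnames(tree$edge) <- NULL
    class(tree) <- "phylo"
    validate_phylo_tree(tree)
    tree
  })
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Leaf values are drawn directly from the matrix-normal distribution implied
#' by Brownian motion with evolutionary rate matrix `rate_matrix` on the
#' lambda-transformed phylogenetic covariance: the leaf-value covariance
#' between species `i`, `j` for traits `a`, `b` is
#' `V_lambda[i, j] * rate_matrix[a, b]`. Drawing from the transformed
#' covariance (via its Cholesky root) honors lambda exactly, which
#' branch-wise simulation cannot do for `lambda < 1`. Traits listed in
#' `count_traits` are rounded and floored at zero to emulate gene counts.
#'
#' @param tree A `"phylo"` tree with at least 3 leaves.
#' @param rate_matrix Symmetric positive semi-definite k x k matrix of
#'   evolutionary (co)variances per unit branch length; a single number is
#'   taken as a 1-trait rate.
#' @param lambda True Pagel's lambda in `[0, 1]`.
#' @param root_state Numeric vector of length k, the trait values at the root.
#' @param count_traits Indices (or names matching `colnames(rate_matrix)`) of
#'   traits to round to non-negative integers.
#' @param seed Integer seed (mandatory).
#' @return Data frame of leaf trait values, rows named by leaf label.
#' @export
simulate_bm_traits <- function(tree, rate_matrix, lambda = 1, root_state = 0,
                               count_traits = integer(0), seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  validate_phylo_tree(tree)
  if (length(tree$tip.label) < 3L) stop("tree must have at least 3 leaves")
  if (is.numeric(rate_matrix) && is.null(dim(rate_matrix)))
    rate_matrix <- matrix(rate_matrix, 1L, 1L)
  k <- ncol(rate_matrix)
  if (!isSymmetric(unname(rate_matrix)))
    stop("'rate_matrix' must be symmetric")
  ev <- eigen(rate_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("'rate_matrix' must be positive semi-definite")
  if (length(root_state) == 1L) root_state <- rep(root_state, k)
  stopifnot(length(root_state) == k)

  V <- lambda_transform(phylo_vcv(tree), lambda)$V
  n <- nrow(V)
  jitter <- 1e-12 * max(diag(V))
  L <- chol(V + diag(jitter, n))
  # symmetric square root so a PSD (possibly singular) rate matrix is exact
  re <- eigen(rate_matrix, symmetric = TRUE)
  A <- diag(sqrt(pmax(re$values, 0)), k) %*% t(re$vectors)

  X <- withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(n * k), n, k)
    t(L) %*% Z %*% A
  })
  X <- sweep(X, 2L, root_state, "+")
  colnames(X) <- colnames(rate_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("trait", seq_len(k))
  if (length(count_traits)) {
    idx <- if (is.character(count_traits)) match(count_traits, colnames(X))
           else as.integer(count_traits)
    for (j in idx) X[, j] <- pmax(0, round(X[, j]))
  }
  out <- as.data.frame(X)
  rownames(out) <- tree$tip.label
  out
}

#' Null-calibration battery for the estimators
#'
#' Simulates pairs of *independent* Brownian traits (zero evolutionary
#' cross-covariance) and records how often each method rejects at the
#' nominal level: Pearson correlation (no phylogenetic correction),
#' independent-contrasts regression, and PGLS at lambda = 1, all with the
#' `"standard"` df convention. Under the Brownian null the two corrected
#' methods should reject at the nominal rate, while the naive Pearson test
#' over-rejects when the tree induces strong covariance.
#'
#' @param n_taxa Taxa per replicate (used when `tree` is `NULL`).
#' @param n_replicates Number of simulated datasets (`> 0`).
#' @param birth_rate Yule birth rate for per-replicate trees.
#' @param tree Optional fixed `"phylo"` tree used for every replicate;
#'   when `NULL` a fresh Yule tree is simulated each time.
#' @param lambda True lambda of the simulated traits.
#' @param alpha Nominal significance level.
#' @param seed Integer seed (mandatory).
#' @return Data frame, one row per method, with the empirical rejection rate
#'   and an exact binomial 95% confidence interval.
#' @export
simulate_null_battery <- function(n_taxa = 14, n_replicates, birth_rate = 1,
                                  tree = NULL, lambda = 1, alpha = 0.05,
                                  seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!is.numeric(n_replicates) || n_replicates < 1L)
    stop("'n_replicates' must be a positive integer")
  n_replicates <- as.integer(n_replicates)

  seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max, 2L * n_replicates),
           n_replicates, 2L)
  })
  rej <- matrix(FALSE, n_replicates, 3L,
                dimnames = list(NULL, c("pearson", "fic", "pgls")))
  R0 <- diag(2)
  for (r in seq_len(n_replicates)) {
    tr <- if (is.null(tree))
      simulate_yule_tree(n_taxa, birth_rate, seed = seeds[r, 1L]) else tree
    X <- simulate_bm_traits(tr, R0, lambda = lambda, seed = seeds[r, 2L])
    x <- stats::setNames(X[[1L]], rownames(X))
    y <- stats::setNames(X[[2L]], rownames(X))
    rej[r, "pearson"] <- pearson_correlation(x, y, "standard")$p < alpha
    cx <- felsenstein_contrasts(tr, x)
    cy <- felsenstein_contrasts(tr, y)
    rej[r, "fic"] <- fic_regression(cx, cy, "standard")$p_values[["x"]] < alpha
    V <- phylo_vcv(tr)
    dat <- data.frame(y = y[V$taxa], x = x[V$taxa], row.names = V$taxa)
    fit <- pgls_fit(y ~ x, dat, V, lambda = 1, df_convention = "standard")
    rej[r, "pgls"] <- fit$p_values[["x"]] < alpha
  }
  out <- do.call(rbind, lapply(colnames(rej), function(m) {
    hits <- sum(rej[, m])
    ci <- stats::binom.test(hits, n_replicates)$conf.int
    data.frame(method = m, n_replicates = n_replicates, rejections = hits,
               rate = hits / n_replicates, ci_lower = ci[1L],
               ci_upper = ci[2L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
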