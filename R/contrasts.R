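#' Felsenstein's independent contrasts
#'
#' Standardized contrasts for one continuous trait, by the classical pruning
#' recursion: at each internal node the two daughter values `x1`, `x2` (tip
#' values or reconstructed ancestral values) with adjusted branch lengths
#' `v1`, `v2` yield the contrast `(x1 - x2) / sqrt(v1 + v2)`; the ancestral
#' value is the variance-weighted average of the daughters and the node's own
#' branch is lengthened by `v1 * v2 / (v1 + v2)`. Under Brownian motion the
#' contrasts are independent with unit variance.
#'
#' Polytomies are first resolved deterministically ([resolve_polytomies()]).
#' Children at every node are processed in order of smallest leaf label, so
#' the output order is reproducible; each contrast is tagged with a node id
#' built from the smallest leaf label on either side. Expected variances are
#' floored at `1e-12` so zero-length branches cannot divide by zero.
#'
#' @param tree A `"phylo"` tree.
#' @param trait Named numeric vector with one value per leaf label.
#' @return An object of class `"contrast_set"`: `contrasts` (standardized,
#'   one per internal node of the resolved tree), `expected_variances` (the
#'   branch-length sums before standardization), `node_ids`, `n_taxa`.
#' @export
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' felsenstein_contrasts(tr, c(A = 3, B = 1))$contrasts  # (3-1)/sqrt(2)
felsenstein_contrasts <- function(tree, trait) {
  validate_phylo_tree(tree)
  if (is.null(names(trait)))
    stop("'trait' must be a named vector (names = leaf labels)")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("trait value missing for leaf: ", paste(missing, collapse = ", "))
  if (anyNA(trait[tree$tip.label]))
    stop("trait contains NA for leaf: ",
         paste(tree$tip.label[is.na(trait[tree$tip.label])], collapse = ", "))
  n_taxa <- length(tree$tip.label)
  if (n_taxa < 2L) stop("contrasts need at least 2 leaves")

  tree <- resolve_polytomies(tree)
  n_tip <- length(tree$tip.label)
  kids <- children_list(tree)
  elen <- edge_length_by_child(tree)
  x <- as.numeric(trait[tree$tip.label])

  eps <- 1e-12
  contrasts <- numeric(0)
  variances <- numeric(0)
  node_ids <- character(0)

  # returns list(value, v_extra, min_label); children ordered by min label
  visit <- function(node) {
    if (node <= n_tip)
      return(list(value = x[node], v_extra = 0, min_label = tree$tip.label[node]))
    ch <- kids[[node]]
    res <- lapply(ch, visit)
    ord <- order(vapply(res, function(r) r$min_label, character(1L)))
    res <- res[ord]
    ch <- ch[ord]
    v1 <- elen[ch[1L]] + res[[1L]]$v_extra
    v2 <- elen[ch[2L]] + res[[2L]]$v_extra
    vsum <- max(v1 + v2, eps)
    contrasts[[length(contrasts) + 1L]] <<-
      (res[[1L]]$value - res[[2L]]$value) / sqrt(vsum)
    variances[[length(variances) + 1L]] <<- vsum
    node_ids[[length(node_ids) + 1L]] <<-
      paste(res[[1L]]$min_label, res[[2L]]$min_label, sep = "|")
    # difference form of the variance-weighted average: exact when the
    # daughters agree, so a constant trait yields contrasts of exactly 0
    v1e <- max(v1, eps); v2e <- max(v2, eps)
    anc <- res[[2L]]$value +
      (res[[1L]]$value - res[[2L]]$value) * v2e / (v1e + v2e)
    list(value = anc, v_extra = v1e * v2e / (v1e + v2e),
         min_label = res[[1L]]$min_label)
  }
  root <- tree_root(tree)
  if (length(kids[[root]]) == 0L) stop("degenerate tree")
  visit(root)

  structure(list(contrasts = contrasts, expected_variances = variances,
                 node_ids = node_ids, n_taxa = n_taxa),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("Independent contrasts: %d contrasts from %d taxa\n",
              length(x$contrasts), x$n_taxa))
  print(data.frame(node = x$node_ids, contrast = x$contrasts,
                   expected_variance = x$expected_variances), ...)
  invisible(x)
}

#' Regression through the origin on independent contrasts
#'
#' Fits the no-intercept regression of `y` contrasts on `x` contrasts, the
#' standard way of estimating an evolutionary regression slope from
#' independent contrasts. Each contrast pair is first oriented so the `x`
#' contrast is non-negative (positivization; pairs with an exactly zero `x`
#' contrast keep their original orientation), which does not change the slope
#' or its standard error.
#'
#' @param x_contrasts,y_contrasts `"contrast_set"` objects from the same tree
#'   (identical node order; checked via node ids).
#' @param df_convention `"paper"` uses `n_taxa - 3` degrees of freedom (one
#'   for computing contrasts, two for a slope and an intercept), the
#'   convention of the study being reproduced; `"standard"` uses
#'   `n_contrasts - 1`, the usual through-the-origin choice.
#' @return A `"gls_fit"` object (slope, SE, t, df, two-tailed p, residuals).
#' @export
fic_regression <- function(x_contrasts, y_contrasts,
                           df_convention = c("paper", "standard")) {
  df_convention <- match.arg(df_convention)
  stopifnot(inherits(x_contrasts, "contrast_set"),
            inherits(y_contrasts, "contrast_set"))
  if (!identical(x_contrasts$node_ids, y_contrasts$node_ids))
    stop("contrast sets come from different trees or node orders")
  xc <- x_contrasts$contrasts
  yc <- y_contrasts$contrasts
  flip <- xc < 0
  xc[flip] <- -xc[flip]
  yc[flip] <- -yc[flip]
  sxx <- sum(xc^2)
  if (sxx <= 0)
    stop("degenerate fit: all x-contrasts are zero")
  slope <- sum(xc * yc) / sxx
  rss <- sum((yc - slope * xc)^2)
  n_c <- length(xc)
  df <- if (df_convention == "paper") x_contrasts$n_taxa - 3L else n_c - 1L
  if (df < 1L) stop("non-positive residual degrees of freedom")
  s2 <- rss / df
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  p <- student_t_two_tailed_p(tval, df)
  fitted <- slope * xc
  r2 <- if (sum(yc^2) > 0) 1 - rss / sum(yc^2) else NA_real_
  new_gls_fit(coefficients = c(x = slope), standard_errors = c(x = se),
              t_values = c(x = tval), df = df, p_values = c(x = p),
              lambda = NA_real_, lambda_mode = "contrasts",
              sigma2 = s2, log_likelihood = NA_real_,
              residuals = yc - fitted, r2 = max(0, min(1, r2)),
              n = n_c, method = "FIC",
              df_convention = df_convention)
}
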