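#' Parse a Newick tree description
#'
#' Reads a single rooted Newick string into a `"phylo"`-style tree object
#' (edge matrix, `edge.length`, `tip.label`, `Nnode`), the standard container
#' for rooted phylogenies in R. Square-bracket comments are stripped, quoted
#' labels (single quotes, `''` escape) are accepted, and internal-node labels
#' are retained in `node.label` but play no role in any analysis. Unary
#' internal nodes are collapsed with their branch lengths summed.
#'
#' Parse failures report the 1-based character position of the offending
#' token in the original string (comments included), so a transcription error
#' in a tree file can be located directly.
#'
#' @param text A length-one character vector holding one Newick description
#'   terminated by a semicolon. Every non-root branch must carry a branch
#'   length; lengths must be non-negative.
#' @return An object of class `"phylo"`: a rooted tree whose leaf labels are
#'   unique and non-empty. A branch length on the root, if present, is stored
#'   as `root.edge` and ignored by all covariance computations.
#' @seealso [write_newick()], [read_newick()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")

  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n_char <- length(chars)

  # strip [...] comments, keeping a map back to original positions
  keep <- rep(TRUE, n_char)
  depth <- 0L
  for (i in seq_len(n_char)) {
    ch <- chars[i]
    if (ch == "[") {
      depth <- depth + 1L
      keep[i] <- FALSE
    } else if (ch == "]") {
      if (depth == 0L)
        stop(sprintf("newick parse error at position %d: unmatched ']'", i))
      depth <- depth - 1L
      keep[i] <- FALSE
    } else if (depth > 0L) {
      keep[i] <- FALSE
    }
  }
  if (depth > 0L)
    stop("newick parse error: unterminated '[' comment")

  src <- chars[keep]
  pos <- which(keep)              # original position of src[i]
  # drop whitespace outside quotes lazily during scanning instead

  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$n <- length(src)

  peek <- function() if (st$i <= st$n) src[st$i] else ""
  advance <- function() st$i <- st$i + 1L
  here <- function() if (st$i <= st$n) pos[st$i] else n_char + 1L
  skip_ws <- function() {
    while (st$i <= st$n && grepl("^\\s$", src[st$i])) advance()
  }
  fail <- function(msg) {
    stop(sprintf("newick parse error at position %d: %s", here(), msg))
  }

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      p0 <- here()
      advance()
      out <- character()
      repeat {
        if (st$i > st$n)
          stop(sprintf("newick parse error at position %d: unterminated quoted label", p0))
        ch <- peek()
        advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      paste(out, collapse = "")
    } else {
      out <- character()
      while (st$i <= st$n && !(peek() %in% c("(", ")", ",", ":", ";")) &&
             !grepl("^\\s$", peek())) {
        out <- c(out, peek())
        advance()
      }
      paste(out, collapse = "")
    }
  }

  read_length <- function() {
    skip_ws()
    p0 <- here()
    out <- character()
    while (st$i <= st$n && grepl("^[0-9eE.+-]$", peek())) {
      out <- c(out, peek())
      advance()
    }
    tok <- paste(out, collapse = "")
    val <- suppressWarnings(as.numeric(tok))
    if (!nzchar(tok) || is.na(val))
      stop(sprintf("newick parse error at position %d: expected a branch length, got '%s'",
                   p0, tok))
    if (val < 0)
      stop(sprintf("newick parse error at position %d: negative branch length %s",
                   p0, tok))
    val
  }

  # recursive descent; each node is list(children, label, length)
  read_subtree <- function() {
    skip_ws()
    if (peek() == "(") {
      p_open <- here()
      advance()
      children <- list(read_subtree())
      repeat {
        skip_ws()
        if (peek() == ",") {
          advance()
          children[[length(children) + 1L]] <- read_subtree()
        } else if (peek() == ")") {
          advance()
          break
        } else {
          stop(sprintf("newick parse error at position %d: unbalanced parentheses (group opened at %d)",
                       here(), p_open))
        }
      }
      lab <- read_label()
      len <- NA_real_
      skip_ws()
      if (peek() == ":") { advance(); len <- read_length() }
      list(children = children, label = lab, length = len, pos = p_open)
    } else {
      p0 <- here()
      lab <- read_label()
      if (!nzchar(lab))
        stop(sprintf("newick parse error at position %d: empty leaf label", p0))
      len <- NA_real_
      skip_ws()
      if (peek() == ":") { advance(); len <- read_length() }
      list(children = list(), label = lab, length = len, pos = p0)
    }
  }

  root <- read_subtree()
  skip_ws()
  if (peek() != ";")
    fail("missing terminal semicolon")
  advance()
  skip_ws()
  if (st$i <= st$n)
    fail("trailing characters after semicolon")

  tree <- nested_to_phylo(root)
  validate_phylo_tree(tree)
  tree
}

# Convert the nested parser structure to an ape-compatible "phylo" list.
# Unary chains are collapsed (lengths summed); a length on the root becomes
# root.edge. Errors if any non-root branch lacks a length.
nested_to_phylo <- function(root) {
  # collapse unary internal nodes
  collapse1 <- function(nd) {
    while (length(nd$children) == 1L) {
      child <- nd$children[[1L]]
      if (!is.na(nd$length)) {
        child$length <- if (is.na(child$length)) nd$length else child$length + nd$length
      }
      nd <- child
    }
    if (length(nd$children) > 0L)
      nd$children <- lapply(nd$children, collapse1)
    nd
  }
  root <- collapse1(root)

  count_tips <- function(nd) {
    if (length(nd$children) == 0L) 1L else sum(vapply(nd$children, count_tips, 1L))
  }
  n_tip <- count_tips(root)

  st <- new.env(parent = emptyenv())
  st$tip_i <- 0L
  st$node_i <- n_tip  # internal ids start at n_tip + 1
  st$tip_label <- character(n_tip)
  st$node_label <- character()
  st$parent <- integer()
  st$child <- integer()
  st$len <- numeric()

  assign_ids <- function(nd) {
    if (length(nd$children) == 0L) {
      st$tip_i <- st$tip_i + 1L
      st$tip_label[st$tip_i] <- nd$label
      st$tip_i
    } else {
      st$node_i <- st$node_i + 1L
      id <- st$node_i
      st$node_label[id - n_tip] <- nd$label
      for (ch in nd$children) {
        cid <- assign_ids(ch)
        st$parent <- c(st$parent, id)
        st$child <- c(st$child, cid)
        if (is.na(ch$length))
          stop(sprintf("newick parse error at position %d: missing branch length", ch$pos))
        st$len <- c(st$len, ch$length)
      }
      id
    }
  }

  if (length(root$children) == 0L) {
    # single-leaf tree: degenerate but supported ("A:1;")
    tree <- list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = if (is.na(root$length)) 0 else root$length,
                 tip.label = root$label,
                 Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }

  assign_ids(root)
  tree <- list(edge = cbind(st$parent, st$child),
               edge.length = st$len,
               tip.label = st$tip_label,
               Nnode = st$node_i - n_tip)
  dimnames(tree$edge) <- NULL
  if (any(nzchar(st$node_label))) tree$node.label <- st$node_label
  if (!is.na(root$length)) tree$root.edge <- root$length
  class(tree) <- "phylo"
  tree
}

# Structural checks shared by every constructor of a tree object.
validate_phylo_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 1L) stop("tree has no leaves")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("every leaf must carry a non-empty label")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  # connectivity: every non-root node has exactly one parent
  ids <- seq_len(n_tip + tree$Nnode)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(root) != 1L) stop("tree must have exactly one root")
  tab <- tabulate(tree$edge[, 2L], nbins = max(ids))
  if (any(tab[setdiff(ids, root)] != 1L))
    stop("tree is not connected: some node lacks a single parent")
  invisible(tree)
}

#' Write a tree as a Newick string
#'
#' Inverse of [parse_newick()]: branch lengths are printed with enough
#' significant digits (>= 10) that a parse/write round trip preserves them
#' to full precision. Labels are written unquoted unless they contain Newick
#' syntax characters or whitespace.
#'
#' @param tree A `"phylo"` tree.
#' @return A length-one character string ending in `";"`.
#' @export
#' @examples
#' write_newick(parse_newick("(A:0.5,B:0.5);"))
write_newick <- function(tree) {
  validate_phylo_tree(tree)
  n_tip <- length(tree$tip.label)

  quote_if_needed <- function(lab) {
    if (grepl("[](),:;'[ \t]", lab))
      paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
    else lab
  }
  # shortest decimal representation that parses back to the same double
  fmt <- function(x) {
    for (d in c(10L, 15L, 17L)) {
      s <- sprintf("%.*g", d, x)
      if (as.numeric(s) == x) return(s)
    }
    s
  }

  if (n_tip == 1L) {
    return(paste0(quote_if_needed(tree$tip.label[1L]), ":",
                  fmt(tree$edge.length[1L]), ";"))
  }

  kids <- children_list(tree)
  elen <- edge_length_by_child(tree)
  rec <- function(node) {
    if (node <= n_tip) {
      quote_if_needed(tree$tip.label[node])
    } else {
      inner <- vapply(kids[[node]], function(ch) {
        paste0(rec(ch), ":", fmt(elen[ch]))
      }, character(1L))
      paste0("(", paste(inner, collapse = ","), ")")
    }
  }
  root <- tree_root(tree)
  out <- rec(root)
  if (!is.null(tree$root.edge)) out <- paste0(out, ":", fmt(tree$root.edge))
  paste0(out, ";")
}

#' Read or write one tree per Newick file
#'
#' @param path Path of a text file holding a single Newick description
#'   (surrounding whitespace tolerated).
#' @return `read_newick()` returns a `"phylo"` tree; `write_newick_file()`
#'   invisibly returns `path`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(trimws(txt))
}

#' @rdname read_newick
#' @param tree A `"phylo"` tree.
#' @export
write_newick_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}
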