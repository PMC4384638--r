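## Species trait tables: loading, validation, alignment with a tree, and
## access to the packaged study fixtures.

trait_table_columns <- c("species", "cd33rsiglec_count", "klk_count",
                         "tlr_count", "fcgr_count", "max_lifespan_years",
                         "body_weight_grams")

count_columns <- c("cd33rsiglec_count", "klk_count", "tlr_count", "fcgr_count")

#' Gene families analyzed by the study pipeline
#'
#' Maps the trait-table count columns to the display names used in reports:
#' the CD33-related Siglecs and the three negative-control families
#' (kallikreins, Toll-like receptors, IgG Fc receptors).
#' @return Named character vector (column name -> display label).
#' @export
family_labels <- function() {
  c(cd33rsiglec_count = "CD33rSIGLECs", klk_count = "KLKs",
    tlr_count = "TLRs", fcgr_count = "IgG Fc receptors")
}

#' Load and validate a species trait table
#'
#' Reads a comma-separated table with the schema
#' `species,cd33rsiglec_count,klk_count,tlr_count,fcgr_count,max_lifespan_years,body_weight_grams`:
#' one row per species with integer gene counts for the four families,
#' maximum lifespan in years and average adult body weight in grams. Rows
#' are sorted alphabetically by species and species names become row names.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `"species_traits"`.
#' @export
load_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(tab)
}

#' @rdname load_trait_table
#' @param tab A data frame with the trait-table schema.
#' @export
validate_trait_table <- function(tab) {
  missing_cols <- setdiff(trait_table_columns, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  tab <- tab[trait_table_columns]
  tab$species <- trimws(as.character(tab$species))
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup))
    stop("duplicate species row(s): ", paste(dup, collapse = ", "))
  for (cc in setdiff(trait_table_columns, "species")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v)) {
      bad <- tab$species[is.na(v)]
      stop(sprintf("non-numeric value in column '%s', row(s): %s",
                   cc, paste(bad, collapse = ", ")))
    }
    tab[[cc]] <- v
  }
  for (cc in count_columns) {
    if (any(tab[[cc]] < 0) || any(tab[[cc]] != round(tab[[cc]]))) {
      bad <- tab$species[tab[[cc]] < 0 | tab[[cc]] != round(tab[[cc]])]
      stop(sprintf("column '%s' must hold non-negative integers, row(s): %s",
                   cc, paste(bad, collapse = ", ")))
    }
    tab[[cc]] <- as.integer(tab[[cc]])
  }
  for (cc in c("max_lifespan_years", "body_weight_grams")) {
    if (any(tab[[cc]] <= 0)) {
      bad <- tab$species[tab[[cc]] <= 0]
      stop(sprintf("column '%s' must be strictly positive (log-transformable), row(s): %s",
                   cc, paste(bad, collapse = ", ")))
    }
  }
  tab <- tab[order(tab$species), , drop = FALSE]
  rownames(tab) <- tab$species
  class(tab) <- c("species_traits", "data.frame")
  tab
}

#' @export
print.species_traits <- function(x, ...) {
  cat(sprintf("Species trait table: %d species\n", nrow(x)))
  NextMethod()
}

#' Align a trait table with a tree
#'
#' Prunes the tree to the table's species and reorders the table rows to the
#' pruned tree's taxon order, so traits and covariance matrices index the
#' same species in the same order.
#'
#' @param tab A `"species_traits"` table (or data frame with that schema).
#' @param tree A `"phylo"` tree whose leaf set contains the table's species.
#' @return A list with `traits` (reordered table) and `tree` (pruned tree).
#' @export
align_table_and_tree <- function(tab, tree) {
  tab <- validate_trait_table(as.data.frame(tab))
  absent <- setdiff(tab$species, tree$tip.label)
  if (length(absent))
    stop("species absent from tree: ", paste(absent, collapse = ", "))
  pruned <- prune_to_taxa(tree, tab$species)
  traits <- tab[pruned$tip.label, , drop = FALSE]
  stopifnot(identical(rownames(traits), pruned$tip.label))
  list(traits = traits, tree = pruned)
}

#' Packaged study fixtures
#'
#' The packaged 14-mammal fixture is a synthetic stand-in for the original
#' study inputs, which are published only as figures: species names, AnAge
#' maximum lifespans and body weights are genuine, gene counts are
#' literature-informed, and the two chronograms carry divergence times in the
#' range of published mammal supertrees (see the package vignette). The
#' fixture reproduces the study's qualitative structure, not its printed
#' statistics.
#'
#' @return `study_trait_table()`: the 14-species `"species_traits"` table.
#' @export
study_trait_table <- function() {
  load_trait_table(system.file("extdata", "species_traits_synthetic.csv",
                               package = "phylofam", mustWork = TRUE))
}

#' @rdname study_trait_table
#' @param which `"I"` or `"II"`: which of the two alternative chronograms.
#' @return `study_tree()`: a 14-leaf ultrametric `"phylo"` tree.
#' @export
study_tree <- function(which = c("I", "II")) {
  which <- match.arg(which)
  fn <- if (which == "I") "tree_I_synthetic.nwk" else "tree_II_synthetic.nwk"
  read_newick(system.file("extdata", fn, package = "phylofam",
                          mustWork = TRUE))
}

#' @rdname study_trait_table
#' @return `primate_additions()`: CD33rSIGLEC counts for three later-sequenced
#'   short-lived primates (counts as reported; lifespans must be supplied by
#'   the user from AnAge before these rows can enter a refit).
#' @export
primate_additions <- function() {
  utils::read.csv(system.file("extdata", "primate_additions_synthetic.csv",
                              package = "phylofam", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Read a flat key-value analysis configuration
#'
#' Parses `key = value` lines (comments with `#`, blank lines ignored) into a
#' named list merged over the documented defaults: `trait_table_path`,
#' `tree_i_path`, `tree_ii_path`, `families` (comma-separated count-column
#' names), `lambda` (number or `ml`), `df_convention`, `log_base`,
#' `exclude` (comma-separated species), `seed`, `out`.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values (character).
#' @export
read_analysis_config <- function(path) {
  defaults <- list(trait_table_path = "", tree_i_path = "", tree_ii_path = "",
                   families = paste(count_columns, collapse = ","),
                   lambda = "1", df_convention = "paper", log_base = "10",
                   exclude = "", seed = "1", out = "")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    defaults[[key]] <- val
  }
  defaults
}
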