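#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' analysis relies on: unique tip labels, non-negative branch lengths and
#' a rooted topology. Polytomies are preserved.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Newick string, used instead of `path` when given.
#' @param default_branch_length If the tree has no branch lengths, use
#'   this value for every edge instead of failing (`NULL`, the default,
#'   fails).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL, default_branch_length = NULL) {
  tree <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick: no tree could be parsed")
  if (is.null(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths (set default_branch_length to supply them)")
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # the basal node of the parsed Newick is taken as the root; basal
  # polytomies (star trees) are allowed
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path; if `NULL` the Newick string is returned.
#' @param digits Printed precision for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Prune a phylogeny to a species set
#'
#' Drops all tips outside `keep` and collapses the resulting degree-2
#' internal nodes, summing branch lengths, so every kept tip retains its
#' root-to-tip distance.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L)
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 species to keep")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic covariance matrix with Pagel's lambda scaling
#'
#' The Brownian-motion covariance of tip values: entry (i, j) is the
#' shared path length from the root to the most recent common ancestor of
#' tips i and j; the diagonal holds root-to-tip distances. Pagel's lambda
#' multiplies the off-diagonal entries, so `lambda = 0` gives a diagonal
#' (star-like) matrix and `lambda = 1` the full Brownian covariance.
#' Polytomies are handled natively.
#'
#' @param tree A `phylo` object.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @return An object of class `phylo_cov`: list with `V` (the matrix,
#'   species in rownames), `species`, `lambda`, and a cache environment
#'   used to share spectral decompositions across repeated model fits.
#' @export
phylo_cov <- function(tree, lambda = 1) {
  validate_tree(tree)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  V <- ape::vcv.phylo(tree)
  if (lambda != 1) {
    d <- diag(V)
    V <- V * lambda
    diag(V) <- d
  }
  structure(list(V = V, species = rownames(V), lambda = lambda,
                 cache = new.env(parent = emptyenv())),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic covariance:", length(x$species), "species, lambda =",
      x$lambda, "\n")
  invisible(x)
}

as_cov_matrix <- function(cov) {
  if (inherits(cov, "phylo_cov")) return(cov$V)
  if (inherits(cov, "phylo")) return(ape::vcv.phylo(cov))
  if (is.matrix(cov)) return(cov)
  stop("cov must be a phylo_cov, phylo tree, or matrix")
}

cov_cache <- function(cov) {
  if (inherits(cov, "phylo_cov")) cov$cache else new.env(parent = emptyenv())
}

#' Normalise species names
#'
#' Exact matching after replacing spaces with underscores, collapsing
#' repeated separators and case-folding, the convention used to reconcile
#' trait tables with tree tip labels.
#'
#' @param x Character vector of species names.
#' @return Normalised names.
#' @export
normalize_species <- function(x) {
  x <- gsub("[ _]+", "_", trimws(x))
  tolower(x)
}

#' Match trait-table species to tree tips
#'
#' @param species Character vector from a trait table.
#' @param tips Tree tip labels.
#' @return List with `matched` (named character: table name -> tip label),
#'   `unmatched_species` and `unmatched_tips`. A mismatch report is always
#'   produced via `message()`.
#' @export
match_species <- function(species, tips) {
  ns <- normalize_species(species)
  nt <- normalize_species(tips)
  idx <- match(ns, nt)
  matched <- stats::setNames(tips[idx], species)[!is.na(idx)]
  res <- list(matched = matched,
              unmatched_species = species[is.na(idx)],
              unmatched_tips = tips[!nt %in% ns])
  message(sprintf("species matching: %d matched, %d table-only, %d tree-only",
                  length(res$matched), length(res$unmatched_species),
                  length(res$unmatched_tips)))
  res
}

#' Read a species trait table
#'
#' Reads a CSV (header row, UTF-8) of species trait data. The `schema`
#' maps the roles the analysis needs onto column names. Rows with missing
#' values in any mapped column are dropped (complete-case policy) and the
#' number of dropped rows is reported.
#'
#' @param path CSV file path.
#' @param schema Named list with entries `species`, `urban`, and
#'   optionally `order`, `realm`, `traits` (character vector of continuous
#'   trait columns) and `diet` (character vector of diet-proportion
#'   columns, from which a Shannon diet-diversity column `DD` is derived).
#' @param diet_renormalize Passed to [shannon_diversity()]: renormalise
#'   diet proportions that do not sum to 1 (with a warning) instead of
#'   failing.
#' @return A data.frame with one row per species; attribute `dropped`
#'   holds the number of incomplete rows removed.
#' @export
read_trait_table <- function(path, schema, diet_renormalize = FALSE) {
  stopifnot(is.list(schema), !is.null(schema$species), !is.null(schema$urban))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- unique(c(schema$species, schema$urban, schema$order, schema$realm,
                     schema$traits, schema$diet))
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0L)
    stop("columns missing from ", path, ": ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab[[schema$species]]))
    stop("duplicate species in trait table: ",
         paste(unique(tab[[schema$species]][duplicated(tab[[schema$species]])]),
               collapse = ", "))
  urb <- tab[[schema$urban]]
  if (is.numeric(urb)) {
    if (!all(urb %in% c(0, 1, NA))) stop("urban column must be 0/1 or a category label")
  } else {
    ok <- c("none", "non-urban", "0", "visitor", "dweller", "both", "1")
    bad <- setdiff(unique(tolower(urb[!is.na(urb)])), ok)
    if (length(bad) > 0L)
      stop("urban column has unrecognised values: ", paste(bad, collapse = ", "))
  }
  if (!is.null(schema$diet)) {
    P <- as.matrix(tab[, schema$diet, drop = FALSE])
    tab$DD <- apply(P, 1L, function(p) {
      if (anyNA(p)) NA_real_ else shannon_diversity(p, renormalize = diet_renormalize)
    })
  }
  check <- unique(c(schema$species, schema$urban, schema$order, schema$realm,
                    schema$traits, if (!is.null(schema$diet)) "DD"))
  cc <- stats::complete.cases(tab[, check, drop = FALSE])
  dropped <- sum(!cc)
  if (dropped > 0L)
    message("dropped ", dropped, " species with incomplete trait information")
  out <- tab[cc, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "schema") <- schema
  out
}
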