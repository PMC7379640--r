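#' Shannon diversity of a diet profile
#'
#' H = -sum(p_i * log p_i) over the diet-category proportions, the
#' standard diet-generalism index. Zero proportions contribute nothing.
#' Natural log by default; `base` switches the unit.
#'
#' @param p Numeric vector of category proportions, each in \[0, 1\],
#'   summing to 1 (tolerance 1e-6).
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @param renormalize If `TRUE`, proportions not summing to 1 are rescaled
#'   with a warning instead of raising an error.
#' @return H, a single number in \[0, log(length(p), base)\].
#' @examples
#' shannon_diversity(rep(0.1, 10)) # log(10)
#' @export
shannon_diversity <- function(p, base = exp(1), renormalize = FALSE) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) stop("p must be numeric, no NA")
  if (any(p < 0) || any(p > 1)) stop("proportions must lie in [0, 1]")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    if (!renormalize) stop("proportions sum to ", format(s), ", not 1")
    if (s <= 0) stop("proportions sum to 0; cannot renormalize")
    warning("renormalizing proportions (sum was ", format(s), ")")
    p <- p / s
  }
  as.numeric(vegan::diversity(p, index = "shannon", base = base))
}

#' Log-transform and standardize trait columns
#'
#' Applies a natural-log transform to the named columns, then z-scores
#' every continuous column within the dataset (mean 0, sd 1). Binary 0/1
#' columns are left untouched. The affine maps are stored so values can
#' be back-transformed.
#'
#' @param data A data.frame of traits (continuous and binary columns).
#' @param vars Columns to standardize; default: all numeric non-binary
#'   columns.
#' @param log_vars Subset of `vars` to log-transform first; values must be
#'   strictly positive.
#' @return The transformed data.frame, with attribute `transforms`: a
#'   per-column list of `(log, center, scale)` consumed by
#'   [unstandardize()].
#' @export
transform_and_standardize <- function(data, vars = NULL,
                                      log_vars = character()) {
  stopifnot(is.data.frame(data))
  if (is.null(vars)) {
    num <- vapply(data, is.numeric, logical(1L))
    binary <- vapply(data, function(x)
      is.numeric(x) && all(x %in% c(0, 1)), logical(1L))
    vars <- names(data)[num & !binary]
  }
  miss <- setdiff(c(vars, log_vars), names(data))
  if (length(miss) > 0L) stop("unknown columns: ", paste(miss, collapse = ", "))
  if (length(setdiff(log_vars, vars)) > 0L)
    stop("log_vars must be a subset of vars")
  tr <- list()
  for (v in vars) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("column not numeric: ", v)
    lg <- v %in% log_vars
    if (lg) {
      if (any(x <= 0)) {
        offender <- rownames(data)[x <= 0]
        if (is.null(offender) || all(offender == as.character(which(x <= 0))))
          offender <- which(x <= 0)
        stop("non-positive values in log-transformed column ", v, ": ",
             paste(utils::head(offender, 5L), collapse = ", "))
      }
      x <- log(x)
    }
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("column is constant, cannot standardize: ", v)
    data[[v]] <- (x - m) / s
    tr[[v]] <- list(log = lg, center = m, scale = s)
  }
  attr(data, "transforms") <- tr
  data
}

#' Invert [transform_and_standardize()] for one column
#'
#' @param x Standardized values.
#' @param transforms The `transforms` attribute of the standardized table.
#' @param var Column name.
#' @return Values on the original scale.
#' @export
unstandardize <- function(x, transforms, var) {
  t <- transforms[[var]]
  if (is.null(t)) stop("no transform recorded for ", var)
  y <- x * t$scale + t$center
  if (t$log) y <- exp(y)
  y
}

#' Assemble a per-order analysis dataset
#'
#' Builds the (standardized design, pruned tree) pair for one taxonomic
#' order and one urban class. Filtering applies, in order: restriction to
#' the order's species present in the tree; complete cases (already
#' enforced by [read_trait_table()]); exclusion of species unambiguously
#' classified in the *other* urban class; restriction of the non-urban
#' background to species occurring in the biogeographic realms where the
#' order's urban species occur (optional). Species recorded as both
#' visitor and dweller count as positives for either class. Datasets with
#' fewer than `min_n` species are skipped (`NULL` returned) with a
#' message.
#'
#' @param table Trait table from [read_trait_table()] (or equivalent),
#'   whose urban column uses labels `none`/`visitor`/`dweller`/`both`.
#' @param tree A `phylo` object covering the species.
#' @param order Taxonomic order to analyse.
#' @param urban_class `"visitor"` or `"dweller"`.
#' @param realm_filter Apply the same-realm restriction to non-urban
#'   species (default `TRUE`; needs a `realm` column in the schema).
#' @param min_n Minimum species count to analyse (default 20).
#' @param log_vars Columns to log-transform before standardization.
#' @param schema Role-to-column map; defaults to the one attached by
#'   [read_trait_table()].
#' @return `NULL` if skipped; otherwise a list with `data` (standardized
#'   design incl. binary `urban` column), `tree` (pruned), `n`, and
#'   `species`.
#' @export
assemble_order_dataset <- function(table, tree, order,
                                   urban_class = c("visitor", "dweller"),
                                   realm_filter = TRUE, min_n = 20,
                                   log_vars = c("body_mass", "brain_mass",
                                                "weaning_age"),
                                   schema = attr(table, "schema")) {
  urban_class <- match.arg(urban_class)
  if (is.null(schema)) stop("no schema available; pass one explicitly")
  other <- setdiff(c("visitor", "dweller"), urban_class)
  sub <- table[table[[schema$order]] == order, , drop = FALSE]
  if (nrow(sub) == 0L) stop("order not present in table: ", order)
  m <- match_species(sub[[schema$species]], tree$tip.label)
  sub <- sub[sub[[schema$species]] %in% names(m$matched), , drop = FALSE]
  status <- tolower(sub[[schema$urban]])
  status[status %in% c("0", "non-urban")] <- "none"
  urban <- as.integer(status %in% c(urban_class, "both", "1"))
  drop <- status == other # unambiguous members of the other class
  if (realm_filter) {
    if (is.null(schema$realm)) stop("realm_filter = TRUE but schema has no realm column")
    realms <- strsplit(as.character(sub[[schema$realm]]), "[;,|]\\s*")
    urb_realms <- unique(unlist(realms[urban == 1L]))
    in_realm <- vapply(realms, function(r) any(r %in% urb_realms), logical(1L))
    drop <- drop | (urban == 0L & !in_realm)
  }
  sub <- sub[!drop, , drop = FALSE]
  urban <- urban[!drop]
  n <- nrow(sub)
  if (n < 2L) stop("fewer than 2 species left after filtering for ", order)
  if (n < min_n) {
    message("skipping ", order, " ", urban_class, ": n = ", n, " < ", min_n)
    return(NULL)
  }
  trait_cols <- unique(c(schema$traits, if ("DD" %in% names(sub)) "DD"))
  design <- sub[, trait_cols, drop = FALSE]
  rownames(design) <- unname(m$matched[sub[[schema$species]]])
  design <- transform_and_standardize(design,
                                      log_vars = intersect(log_vars, trait_cols))
  design$urban <- urban
  ptree <- prune_tree(tree, rownames(design))
  list(data = design, tree = ptree, n = n, species = rownames(design))
}
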