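#' Construct a causal DAG
#'
#' A causal model is a directed acyclic graph whose vertices are trait
#' variables (plus, optionally, one binary outcome vertex) and whose edges
#' are hypothesised causal links `parent -> child`. The number of edges
#' `q` is the number of free path coefficients and enters the CICc penalty.
#'
#' @param edges Either a two-column matrix/data.frame (`from`, `to`) or a
#'   character vector of `"parent -> child"` strings. May be empty.
#' @param vertices Character vector of vertex names. Defaults to the
#'   vertices appearing in `edges`; must be a superset of them. The
#'   declared order is used as the deterministic tie-break in topological
#'   sorting.
#' @return An object of class `causal_dag` with elements `vertices`,
#'   `edges` (two-column character matrix) and `q = nrow(edges)`.
#' @examples
#' d <- causal_dag(c("BM -> BR", "BR -> LS"))
#' topological_order(d)
#' @export
causal_dag <- function(edges = character(), vertices = NULL) {
  em <- parse_edges(edges)
  verts <- unique(c(vertices, as.vector(t(em))))
  if (length(verts) == 0L) stop("a causal_dag needs at least one vertex")
  if (anyDuplicated(verts)) stop("duplicate vertex names")
  if (nrow(em) > 0L) {
    if (any(em[, 1L] == em[, 2L])) stop("self-loops are not allowed")
    key <- paste(em[, 1L], em[, 2L], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges: ",
                                 paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  dag <- structure(list(vertices = verts, edges = em, q = nrow(em)),
                   class = "causal_dag")
  topological_order(dag) # errors on a cycle, naming it
  dag
}

parse_edges <- function(edges) {
  if (is.matrix(edges) || is.data.frame(edges)) {
    if (nrow(edges) > 0L && ncol(edges) < 2L) stop("edges need two columns (from, to)")
    em <- if (nrow(edges) == 0L) matrix(character(), 0L, 2L) else
      if (is.matrix(edges))
        cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
      else cbind(as.character(edges[[1L]]), as.character(edges[[2L]]))
  } else if (is.character(edges)) {
    if (length(edges) == 0L) {
      em <- matrix(character(), 0L, 2L)
    } else {
      parts <- strsplit(edges, "->", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad)) stop("cannot parse edge(s): ", paste(edges[bad], collapse = ", "))
      em <- t(vapply(parts, function(p) trimws(p), character(2L)))
    }
  } else stop("edges must be a character vector or a two-column table")
  colnames(em) <- c("from", "to")
  em
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with ties broken by the declared vertex order, so the
#' result is deterministic for a given `causal_dag`.
#'
#' @param dag A [causal_dag()].
#' @return Character vector of vertices, parents before children.
#' @export
topological_order <- function(dag) {
  stopifnot(inherits(dag, "causal_dag"))
  verts <- dag$vertices
  indeg <- stats::setNames(integer(length(verts)), verts)
  if (nrow(dag$edges) > 0L) {
    tab <- table(factor(dag$edges[, 2L], levels = verts))
    indeg[] <- as.integer(tab)
  }
  out <- character(0)
  remaining <- verts
  while (length(remaining) > 0L) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0L) {
      stop("cycle detected among vertices: ", paste(remaining, collapse = ", "))
    }
    v <- ready[1L] # declared order breaks ties
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    if (nrow(dag$edges) > 0L) {
      ch <- dag$edges[dag$edges[, 1L] == v, 2L]
      for (w in ch) indeg[w] <- indeg[w] - 1L
    }
  }
  out
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("Causal DAG:", length(x$vertices), "vertices,", x$q, "edges (q)\n")
  if (x$q > 0L) {
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  } else cat("  (no edges)\n")
  invisible(x)
}

dag_parents <- function(dag, v) dag$edges[dag$edges[, 2L] == v, 1L]

dag_has_edge <- function(dag, from, to) {
  any(dag$edges[, 1L] == from & dag$edges[, 2L] == to)
}

dag_adjacent <- function(dag, a, b) {
  dag_has_edge(dag, a, b) || dag_has_edge(dag, b, a)
}

#' Add edges to a DAG
#'
#' @param dag A [causal_dag()].
#' @param edges Edges in any form accepted by [causal_dag()].
#' @return A new `causal_dag`.
#' @export
add_edges <- function(dag, edges) {
  em <- parse_edges(edges)
  causal_dag(rbind(dag$edges, em), vertices = dag$vertices)
}

#' Enumerate a candidate model set
#'
#' Starting from a trait-only model (the null hypothesis: no trait causes
#' the outcome), every subset of the candidate direct links
#' `trait -> outcome` is added in turn, giving `2^k` candidate DAGs for
#' `k` candidate links. Subsets are generated by binary counting over the
#' candidate list, so the order is deterministic and the first model is
#' always the trait-only null. Model identifiers are the added link
#' sources joined by `" + "` in the declared candidate order
#' (`"Trait-only"` for the empty subset).
#'
#' @param trait_only A [causal_dag()] over the trait variables (it may
#'   already contain the outcome vertex with no incoming edges).
#' @param candidate_links Character vector of trait names, each a
#'   candidate parent of `outcome`.
#' @param outcome Name of the binary outcome vertex.
#' @return A named list of `causal_dag` objects of length
#'   `2^length(candidate_links)`; class `model_set`.
#' @examples
#' d <- causal_dag(c("BM -> BR"), vertices = c("BM", "BR", "urban"))
#' length(enumerate_models(d, c("BM", "BR"), "urban")) # 4
#' @export
enumerate_models <- function(trait_only, candidate_links, outcome) {
  stopifnot(inherits(trait_only, "causal_dag"))
  if (anyDuplicated(candidate_links)) stop("duplicate candidate links")
  for (v in candidate_links) {
    if (dag_has_edge(trait_only, v, outcome))
      stop("candidate link duplicates a trait-only edge: ", v, " -> ", outcome)
  }
  base <- trait_only
  if (!(outcome %in% base$vertices)) {
    base <- causal_dag(base$edges, vertices = c(base$vertices, outcome))
  }
  if (any(base$edges[, 1L] == outcome))
    stop("outcome vertex must have out-degree 0")
  k <- length(candidate_links)
  models <- vector("list", 2L^k)
  ids <- character(2L^k)
  for (i in seq_len(2L^k)) {
    bits <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(max(k, 1L)) - 1L)))
    sel <- candidate_links[bits[seq_len(k)]]
    m <- base
    if (length(sel) > 0L) {
      m <- causal_dag(rbind(base$edges, cbind(from = sel, to = outcome)),
                      vertices = base$vertices)
    }
    models[[i]] <- m
    ids[i] <- if (length(sel) == 0L) "Trait-only" else paste(sel, collapse = " + ")
  }
  names(models) <- ids
  structure(models, class = c("model_set", "list"),
            outcome = outcome, candidate_links = candidate_links)
}

#' @export
print.model_set <- function(x, ...) {
  cat("Model set:", length(x), "candidate causal models\n")
  cat("  outcome:", attr(x, "outcome"), "\n")
  cat("  candidate links:", paste(attr(x, "candidate_links"), collapse = ", "), "\n")
  invisible(x)
}

#' Shipley d-separation basis set
#'
#' For every non-adjacent unordered vertex pair \{x, y\} the DAG implies
#' the conditional independence x ⊥ y | pa(x) ∪ pa(y) (the pair itself
#' excluded). The basis set lists one such claim per pair, so its size is
#' `choose(|V|, 2) - q`. Each claim designates a regression response: the
#' binary vertex whenever it is in the pair (a binary variable can only be
#' tested as a response), otherwise the vertex later in topological order.
#'
#' @param dag A [causal_dag()].
#' @param binary Name of the binary vertex, or `NULL` if none.
#' @return A data.frame with columns `x`, `y`, `response`, `predictor` and
#'   a list-column `conditioning`.
#' @examples
#' basis_set(causal_dag(c("X -> Y", "Y -> Z"))) # X _||_ Z | Y
#' @export
basis_set <- function(dag, binary = NULL) {
  stopifnot(inherits(dag, "causal_dag"))
  if (!is.null(binary) && !binary %in% dag$vertices)
    stop("binary vertex not in DAG: ", binary)
  topo <- topological_order(dag)
  verts <- dag$vertices
  n <- length(verts)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- verts[i]; b <- verts[j]
        if (dag_adjacent(dag, a, b)) next
        cond <- setdiff(union(dag_parents(dag, a), dag_parents(dag, b)), c(a, b))
        if (!is.null(binary) && binary %in% c(a, b)) {
          resp <- binary
        } else {
          resp <- if (match(a, topo) > match(b, topo)) a else b
        }
        pred <- setdiff(c(a, b), resp)
        rows[[length(rows) + 1L]] <-
          list(x = a, y = b, response = resp, predictor = pred,
               conditioning = sort(cond))
      }
    }
  }
  out <- data.frame(
    x = vapply(rows, `[[`, character(1L), "x"),
    y = vapply(rows, `[[`, character(1L), "y"),
    response = vapply(rows, `[[`, character(1L), "response"),
    predictor = vapply(rows, `[[`, character(1L), "predictor"),
    stringsAsFactors = FALSE
  )
  out$conditioning <- lapply(rows, `[[`, "conditioning")
  out
}

#' Export a DAG in DOT format
#'
#' @param dag A [causal_dag()].
#' @param file Optional path; if omitted the DOT text is returned.
#' @return The DOT source, invisibly when written to a file.
#' @export
dag_to_dot <- function(dag, file = NULL) {
  lines <- c("digraph causal_model {",
             paste0("  \"", dag$vertices, "\";"),
             if (dag$q > 0L)
               paste0("  \"", dag$edges[, 1L], "\" -> \"", dag$edges[, 2L], "\";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
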