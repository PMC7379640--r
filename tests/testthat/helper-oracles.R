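# Independent oracles used to cross-check the package's own machinery.
# These deliberately take different computational routes from the code
# they validate.

# Brute-force d-separation via the moral-graph criterion: x and y are
# d-separated given Z iff they are disconnected in the moralized
# ancestral subgraph of {x, y} union Z with Z removed.
oracle_dsep <- function(edges, vertices, x, y, Z) {
  # ancestors of the query set
  anc <- unique(c(x, y, Z))
  repeat {
    pa <- unique(edges[edges[, 2L] %in% anc, 1L])
    new <- setdiff(pa, anc)
    if (length(new) == 0L) break
    anc <- c(anc, new)
  }
  sub <- edges[edges[, 1L] %in% anc & edges[, 2L] %in% anc, , drop = FALSE]
  # moralize: undirected skeleton plus marriages between co-parents
  und <- rbind(sub, sub[, 2:1, drop = FALSE])
  for (v in anc) {
    pa <- sub[sub[, 2L] == v, 1L]
    if (length(pa) > 1L) {
      pairs <- t(utils::combn(pa, 2L))
      und <- rbind(und, pairs, pairs[, 2:1, drop = FALSE])
    }
  }
  # remove Z, then BFS from x
  keep <- setdiff(anc, Z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  und <- und[und[, 1L] %in% keep & und[, 2L] %in% keep, , drop = FALSE]
  seen <- x
  frontier <- x
  while (length(frontier) > 0L) {
    nb <- unique(und[und[, 1L] %in% frontier, 2L])
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  !(y %in% seen)
}

# Ordinary least squares via the normal equations (oracle for PGLS on a
# star tree / lambda = 0).
oracle_ols <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  r <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  t <- drop(beta) / se
  list(beta = drop(beta), se = se, t = t, p = 2 * pt(-abs(t), df))
}

# Firth-penalized logistic regression by direct numerical maximization of
# the penalized log-likelihood (oracle for the IRLS route when C = I).
oracle_firth_logistic <- function(y, X) {
  negpen <- function(b) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-12)
    -(sum(y * eta - log1p(exp(eta))) +
        0.5 * determinant(crossprod(X, X * W), logarithm = TRUE)$modulus[1L])
  }
  fit <- optim(rep(0, ncol(X)), negpen, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  fit$par
}

# A star phylogeny with unit branch lengths (independence case).
star_tree <- function(n) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# All DAGs over the given vertices whose edges respect the vertex order
# (i -> j only when i precedes j). Every DAG is isomorphic to exactly one
# of these, and d-separation is label-invariant, so this enumerates all
# DAG structures of that size.
ordered_dags <- function(vertices) {
  pairs <- t(utils::combn(vertices, 2L))
  m <- nrow(pairs)
  lapply(seq_len(2L^m) - 1L, function(mask) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    pairs[sel, , drop = FALSE]
  })
}
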