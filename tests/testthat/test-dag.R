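test_that("causal_dag enforces its invariants", {
  d <- causal_dag(c("A -> B", "B -> C"))
  expect_s3_class(d, "causal_dag")
  expect_equal(d$q, 2L)
  expect_error(causal_dag(c("A -> A")), "self-loop")
  expect_error(causal_dag(c("A -> B", "A -> B")), "duplicate edge")
  expect_error(causal_dag(c("A -> B", "B -> A")), "cycle")
  expect_error(causal_dag(c("A -> B", "B -> C", "C -> A")), "cycle")
})

test_that("topological order puts parents first, ties by declaration order", {
  d <- causal_dag(c("A -> C", "B -> C"), vertices = c("B", "A", "C"))
  topo <- topological_order(d)
  expect_equal(topo, c("B", "A", "C"))
  d2 <- causal_dag(c("X -> Y", "Y -> Z", "X -> Z"))
  expect_equal(topological_order(d2), c("X", "Y", "Z"))
})

test_that("model enumeration produces 2^k models by binary counting", {
  td <- example_trait_dag()
  ms <- enumerate_models(td, c("BM", "DD", "BR", "WA", "LS"), "urban")
  expect_length(ms, 32L)
  expect_equal(names(ms)[1L], "Trait-only")
  expect_equal(ms[["Trait-only"]]$q, td$q)
  # q increments by exactly the subset size
  sizes <- vapply(ms, function(m) m$q - td$q, numeric(1L))
  expect_equal(sort(unname(sizes)), rep(0:5, choose(5, 0:5)))
  # all edge sets distinct
  keys <- vapply(ms, function(m)
    paste(sort(paste(m$edges[, 1], m$edges[, 2])), collapse = ";"),
    character(1L))
  expect_equal(anyDuplicated(keys), 0L)
  # every model contains the trait-only edges
  base <- paste(td$edges[, 1], td$edges[, 2])
  expect_true(all(vapply(ms, function(m)
    all(base %in% paste(m$edges[, 1], m$edges[, 2])), logical(1L))))

  expect_length(enumerate_models(td, character(0), "urban"), 1L)
  m8 <- enumerate_models(td, c("BM", "DD", "BR"), "urban")
  expect_length(m8, 8L)
  expect_setequal(names(m8), c("Trait-only", "BM", "DD", "BR", "BM + DD",
                               "BM + BR", "DD + BR", "BM + DD + BR"))
  withbm <- add_edges(td, "BM -> urban")
  expect_error(enumerate_models(withbm, "BM", "urban"), "duplicates")
})

test_that("basis set matches the textbook cases", {
  bs <- basis_set(causal_dag(c("X -> Y", "Y -> Z")))
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$response, "Z")
  expect_equal(bs$predictor, "X")
  expect_equal(bs$conditioning[[1L]], "Y")
  # complete DAG: no non-adjacent pairs
  full <- causal_dag(c("A -> B", "A -> C", "B -> C"))
  expect_equal(nrow(basis_set(full)), 0L)
  # binary vertex is always the response when in the pair
  d <- causal_dag(c("X -> Y"), vertices = c("X", "Y", "urban"))
  bs2 <- basis_set(d, binary = "urban")
  expect_true(all(bs2$response[bs2$x == "urban" | bs2$y == "urban"] == "urban"))
})

test_that("claim count equals choose(V, 2) - q on random DAGs", {
  set.seed(11)
  verts <- paste0("v", 1:6)
  for (i in 1:100) {
    pairs <- t(combn(sample(verts), 2L)) # random topological labeling
    em <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    dag <- causal_dag(em, vertices = verts)
    expect_equal(nrow(basis_set(dag)), choose(6, 2) - dag$q)
  }
})

test_that("basis set is invariant to vertex declaration order", {
  em <- rbind(c("A", "B"), c("B", "D"), c("C", "D"))
  d1 <- causal_dag(em, vertices = c("A", "B", "C", "D"))
  d2 <- causal_dag(em, vertices = c("D", "C", "B", "A"))
  key <- function(bs) sort(paste(pmin(bs$x, bs$y), pmax(bs$x, bs$y),
                                 vapply(bs$conditioning, paste, character(1L),
                                        collapse = ",")))
  expect_equal(key(basis_set(d1)), key(basis_set(d2)))
})

test_that("every emitted claim is a true d-separation (random small DAGs)", {
  set.seed(7)
  verts <- paste0("v", 1:5)
  for (i in 1:60) {
    pairs <- t(combn(sample(verts), 2L))
    em <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    dag <- causal_dag(em, vertices = verts)
    bs <- basis_set(dag)
    if (nrow(bs) == 0L) next
    for (j in seq_len(nrow(bs))) {
      expect_true(oracle_dsep(dag$edges, verts, bs$x[j], bs$y[j],
                              bs$conditioning[[j]]),
                  label = sprintf("claim %s _||_ %s | {%s}", bs$x[j], bs$y[j],
                                  paste(bs$conditioning[[j]], collapse = ",")))
    }
  }
})

test_that("DOT export lists every vertex and edge", {
  d <- causal_dag(c("A -> B"))
  dot <- dag_to_dot(d)
  expect_match(dot, "digraph")
  expect_match(dot, "\"A\" -> \"B\"")
})
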