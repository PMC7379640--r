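test_that("read_newick parses toy trees and keeps polytomies", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  depths <- diag(ape::vcv.phylo(tr))
  expect_equal(unname(depths[tr$tip.label]), c(2, 2, 2), tolerance = 1e-12)

  star <- read_newick(text = "(A:1,B:1,C:1);")
  expect_equal(star$Nnode, 1L) # a single polytomy
  expect_error(read_newick(text = "((A:1,B:1):1"), "malformed")
  expect_error(read_newick(text = "(A,B);"), "branch length")
  nolen <- read_newick(text = "(A,B);", default_branch_length = 1)
  expect_equal(nolen$edge.length, c(1, 1))
})

test_that("newick round-trip preserves topology and branch lengths", {
  set.seed(3)
  tr <- simulate_yule_tree(20, seed = 3)
  txt <- write_newick(tr)
  tr2 <- read_newick(text = txt)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  v1 <- phylo_cov(tr)$V
  v2 <- phylo_cov(tr2)$V[rownames(v1), colnames(v1)]
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("pruning preserves root-to-tip distances", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  p <- prune_tree(tr, c("A", "C"))
  expect_equal(sort(p$tip.label), c("A", "C"))
  expect_equal(unname(diag(ape::vcv.phylo(p))), c(2, 2), tolerance = 1e-12)

  expect_identical(prune_tree(tr, tr$tip.label), tr)
  expect_error(prune_tree(tr, c("A", "Zeta")), "Zeta")

  big <- simulate_yule_tree(50, seed = 9)
  keep <- sample(big$tip.label, 23)
  before <- diag(ape::vcv.phylo(big))[keep]
  after <- diag(ape::vcv.phylo(prune_tree(big, keep)))[keep]
  expect_equal(after, before, tolerance = 1e-10)
})

test_that("phylogenetic covariance has the shared-path-length structure", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  cv <- phylo_cov(tr, 1)$V
  expect_equal(unname(diag(cv)[c("A", "B", "C")]), c(2, 2, 2))
  expect_equal(cv["A", "B"], 1)
  expect_equal(cv["A", "C"], 0)
  expect_equal(cv, t(cv))

  cv0 <- phylo_cov(tr, 0)$V
  expect_true(all(cv0[upper.tri(cv0)] == 0))
  cv5 <- phylo_cov(tr, 0.5)$V
  expect_equal(cv5["A", "B"], 0.5)
  expect_equal(diag(cv5), diag(cv))
  expect_error(phylo_cov(tr, 1.5), "lambda")
})

test_that("covariance is PSD on random Yule trees for any lambda", {
  for (i in 1:20) {
    tr <- simulate_yule_tree(15, seed = 100 + i)
    for (lam in c(0, 0.5, 1)) {
      ev <- eigen(phylo_cov(tr, lam)$V, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10 * max(ev))
    }
  }
})

test_that("vcv commutes with pruning and diagonals equal tree height", {
  tr <- simulate_yule_tree(40, seed = 17)
  keep <- sample(tr$tip.label, 15)
  full <- phylo_cov(tr)$V[keep, keep]
  sub <- phylo_cov(prune_tree(tr, keep))$V[keep, keep]
  expect_equal(sub, full, tolerance = 1e-10)
  d <- diag(phylo_cov(tr)$V)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-8 * max(d)) # ultrametric
})

test_that("species matching normalises separators and case", {
  suppressMessages({
    m <- match_species(c("Vulpes vulpes", "RATTUS_rattus", "Nomatch sp"),
                       c("Vulpes_vulpes", "Rattus_rattus", "Mus_musculus"))
  })
  expect_equal(unname(m$matched), c("Vulpes_vulpes", "Rattus_rattus"))
  expect_equal(m$unmatched_species, "Nomatch sp")
  expect_equal(m$unmatched_tips, "Mus_musculus")
})

test_that("trait tables are read with complete-case filtering", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(species = c("a_a", "b_b", "c_c"), ord = "X",
                   urban = c("none", "visitor", "dweller"),
                   bm = c(10, NA, 30), p1 = c(0.5, 1, 0.2), p2 = c(0.5, 0, 0.8))
  write.csv(df, f, row.names = FALSE)
  schema <- list(species = "species", order = "ord", urban = "urban",
                 traits = "bm", diet = c("p1", "p2"))
  tab <- suppressMessages(read_trait_table(f, schema))
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "dropped"), 1L)
  expect_equal(tab$DD, c(log(2), -0.2 * log(0.2) - 0.8 * log(0.8)),
               tolerance = 1e-12)

  df$species[2] <- "a_a"
  write.csv(df, f, row.names = FALSE)
  expect_error(read_trait_table(f, schema), "duplicate species")
  df$species[2] <- "b_b"; df$urban[2] <- "sometimes"
  write.csv(df, f, row.names = FALSE)
  expect_error(read_trait_table(f, schema), "unrecognised")
})
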