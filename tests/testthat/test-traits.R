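test_that("Shannon diversity hits the closed-form cases", {
  p10 <- c(1, rep(0, 9))
  expect_equal(shannon_diversity(p10), 0)
  expect_equal(shannon_diversity(rep(0.1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(0.5, 0.5, rep(0, 8))), log(2),
               tolerance = 1e-12)
  expect_equal(shannon_diversity(rep(0.1, 10), base = 2), log2(10),
               tolerance = 1e-12)
})

test_that("Shannon diversity is bounded and permutation-invariant", {
  set.seed(21)
  for (i in 1:50) {
    p <- rexp(10); p <- p / sum(p)
    H <- shannon_diversity(p)
    expect_gte(H, 0)
    expect_lte(H, log(10) + 1e-12)
    expect_equal(shannon_diversity(sample(p)), H, tolerance = 1e-12)
  }
})

test_that("invalid diet profiles error unless renormalisation is requested", {
  expect_error(shannon_diversity(c(0.5, 0.4)), "sum")
  expect_warning(H <- shannon_diversity(c(0.25, 0.2), renormalize = TRUE),
                 "renormalizing")
  expect_equal(H, shannon_diversity(c(5 / 9, 4 / 9)), tolerance = 1e-12)
  expect_error(shannon_diversity(c(-0.1, 1.1)), "\\[0, 1\\]")
})

test_that("standardization is exact, idempotent and invertible", {
  set.seed(2)
  d <- data.frame(bm = exp(rnorm(30, 3)), ls = rpois(30, 4) + 1,
                  urban = rbinom(30, 1, 0.3))
  z <- transform_and_standardize(d, log_vars = "bm")
  expect_equal(mean(z$bm), 0, tolerance = 1e-10)
  expect_equal(sd(z$bm), 1, tolerance = 1e-10)
  expect_equal(mean(z$ls), 0, tolerance = 1e-10)
  expect_identical(z$urban, d$urban) # binary column untouched

  z2 <- transform_and_standardize(as.data.frame(z[c("bm", "ls", "urban")]))
  expect_equal(z2$bm, z$bm, tolerance = 1e-10) # idempotent

  back <- unstandardize(z$bm, attr(z, "transforms"), "bm")
  expect_equal(back, d$bm, tolerance = 1e-10)

  d$const <- 5
  expect_error(transform_and_standardize(d), "constant")
  d$const <- NULL; d$bm[1] <- -1
  expect_error(transform_and_standardize(d, log_vars = "bm"), "non-positive")
})

# A small raw table exercising the order/class/realm filters.
make_raw_table <- function() {
  tab <- data.frame(
    species = paste0("sp", 1:30),
    ord = rep(c("Rodentia", "Chiroptera"), c(24, 6)),
    realm = rep(c("PA", "NA", "AT"), 10),
    urban = "none",
    bm = exp(rnorm(30, 2)), ls = runif(30, 1, 6),
    stringsAsFactors = FALSE)
  tab$urban[c(1, 4)] <- "visitor"   # realms PA
  tab$urban[c(2, 8)] <- "dweller"   # realms NA, NA
  tab$urban[5] <- "both"            # realm NA
  attr(tab, "schema") <- list(species = "species", order = "ord",
                              realm = "realm", urban = "urban",
                              traits = c("bm", "ls"))
  tab
}

test_that("order datasets apply class-exclusion and realm rules exactly", {
  set.seed(31)
  tab <- make_raw_table()
  tree <- simulate_yule_tree(30, seed = 1)
  tree$tip.label <- paste0("sp", 1:30)

  ds <- suppressMessages(
    assemble_order_dataset(tab, tree, "Rodentia", "visitor",
                           realm_filter = TRUE, min_n = 2, log_vars = "bm"))
  # brute-force expectation: rodents, minus unambiguous dwellers,
  # non-urban restricted to realms of the positives (PA from 1,4; NA from 5)
  rod <- tab[tab$ord == "Rodentia", ]
  pos <- rod$species[rod$urban %in% c("visitor", "both")]
  realms_pos <- unique(rod$realm[rod$species %in% pos])
  keep <- rod$species[
    !(rod$urban == "dweller") &
      (rod$species %in% pos | rod$realm %in% realms_pos)]
  expect_setequal(ds$species, keep)
  expect_setequal(ds$species[ds$data$urban == 1], pos)
  # design standardized
  expect_equal(mean(ds$data$bm), 0, tolerance = 1e-10)
  expect_equal(sd(ds$data$ls), 1, tolerance = 1e-10)
  # pruned tree matches
  expect_setequal(ds$tree$tip.label, keep)

  # the "both" species counts as positive for either class
  ds2 <- suppressMessages(
    assemble_order_dataset(tab, tree, "Rodentia", "dweller",
                           realm_filter = FALSE, min_n = 2, log_vars = "bm"))
  expect_true(all(c("sp2", "sp5", "sp8") %in% ds2$species[ds2$data$urban == 1]))
  expect_false("sp1" %in% ds2$species) # unambiguous visitor excluded

  # small groups are skipped with a message, not an error
  tab$urban[25] <- "visitor"
  msgs <- capture_messages(
    out <- assemble_order_dataset(tab, tree, "Chiroptera", "visitor",
                                  realm_filter = FALSE, min_n = 20,
                                  log_vars = "bm"))
  expect_true(any(grepl("skipping", msgs)))
  expect_null(out)
})
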