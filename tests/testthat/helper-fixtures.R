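# Writes a small self-contained analysis bundle (tree + traits CSV +
# YAML config) into `dir` and returns the config path. All data are
# generated in code; nothing is stored in the repository.
write_example_bundle <- function(dir, n = 60, seed = 2024) {
  set.seed(seed)
  tree <- simulate_yule_tree(n, seed = seed)
  tree$tip.label <- paste0("sp", seq_len(n))
  sim <- simulate_traits(tree, example_simulation_config(), seed = seed + 1)
  z <- sim$table
  raw <- data.frame(
    species = tree$tip.label,
    ord = "Rodentia",
    realm = sample(c("PA", "NA", "NT"), n, replace = TRUE),
    BM = exp(z$BM + 3), BR = exp(z$BR + 1), WA = exp(z$WA + 2),
    LS = z$LS + 4,
    stringsAsFactors = FALSE)
  diet <- matrix(rexp(10 * n), n, 10)
  diet <- diet / rowSums(diet)
  colnames(diet) <- paste0("d", 1:10)
  raw <- cbind(raw, as.data.frame(diet))
  raw$urban <- "none"
  pos <- which(z$urban == 1)
  raw$urban[pos] <- sample(c("visitor", "dweller", "both"), length(pos),
                           replace = TRUE, prob = c(0.4, 0.4, 0.2))
  write_newick(tree, file.path(dir, "tree.nwk"))
  utils::write.csv(raw, file.path(dir, "traits.csv"), row.names = FALSE)
  cfg <- list(
    tree = "tree.nwk", traits = "traits.csv",
    schema = list(species = "species", order = "ord", realm = "realm",
                  urban = "urban", traits = c("BM", "BR", "WA", "LS"),
                  diet = paste0("d", 1:10)),
    log_vars = c("BM", "BR", "WA"),
    min_n = 20, delta_threshold = 2, alpha = 0.05,
    realm_filter = FALSE, outcome = "urban", seed = 7,
    out_dir = file.path(dir, "results"),
    groups = list(
      list(order = "Rodentia", urban_class = "visitor",
           trait_only = c("BM -> BR", "BM -> WA", "BM -> LS",
                          "BR -> DD", "BR -> WA", "BR -> LS", "LS -> WA"),
           candidate_links = c("BM", "DD", "BR", "WA", "LS"))))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
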