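Package: phylodsep
Title: Phylogenetic Path Analysis with d-Separation Tests and CICc Model
    Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares causal hypotheses about species traits while
    correcting for shared ancestry. Candidate causal structures are
    expressed as directed acyclic graphs, their implied conditional
    independencies are tested with phylogenetic generalized least squares
    (continuous responses) and Firth-penalized phylogenetic logistic
    regression (binary responses), and the resulting p-values are combined
    into Fisher's C. Models are ranked with the small-sample C-statistic
    information criterion (CICc) and path coefficients are combined by
    conditional model averaging over the supported models. Includes
    helpers for trait preparation (diet Shannon diversity,
    log-transformation and standardization, per-clade dataset assembly),
    contingency-table enrichment tests with adjusted residuals, and a
    simulator that generates phylogenies and trait data from a known
    structural equation model with Brownian residuals and a rare binary
    outcome, so the whole pipeline can be validated by parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
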