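#' Fisher's C statistic
#'
#' Combines the p-values of a model's independence claims:
#' `C = -2 * sum(log p_i)`, compared to a chi-square distribution with
#' `2k` degrees of freedom (`k` claims). A large C (small p) rejects the
#' causal model. An empty claim list is the saturated case: `(0, 0, 1)`.
#' p-values of exactly 0 are clipped to 1e-300 with a warning.
#'
#' @param p Numeric vector of claim p-values in (0, 1\].
#' @return List with `C`, `df = 2k` and the d-sep test `p`.
#' @examples
#' fishers_c(c(0.5, 0.5)) # C = 2.7726, df = 4
#' @export
fishers_c <- function(p) {
  if (length(p) == 0L) return(list(C = 0, df = 0L, p = 1))
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("claim p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("claim p-value of 0 clipped to 1e-300")
    p[p == 0] <- 1e-300
  }
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Small-sample C-statistic information criterion
#'
#' `CICc = C + 2 q n / (n - 1 - q)`, where `q` is the number of path
#' coefficients (DAG edges) and `n` the number of species. Plays the role
#' AICc plays in likelihood-based selection; undefined when
#' `n <= q + 1`.
#'
#' @param C Fisher's C of the model.
#' @param q Number of parameters (directed edges) in the path model.
#' @param n Sample size.
#' @return CICc, a single number.
#' @examples
#' cicc(16.53, 9, 47) # 39.39
#' @export
cicc <- function(C, q, n) {
  stopifnot(is.numeric(C), is.numeric(q), is.numeric(n))
  if (any(C < 0)) stop("C must be non-negative")
  if (any(n <= q + 1)) stop("CICc undefined: n must exceed q + 1")
  C + 2 * q * n / (n - 1 - q)
}

#' d-separation test of one causal model
#'
#' Derives the model's basis set, tests every claim with the engine
#' matching the response type (PGLS for continuous responses,
#' Firth-penalized phylogenetic logistic regression when the response is
#' the binary vertex), combines claim p-values into Fisher's C and
#' computes CICc. Alongside the claims, the path-coefficient regressions
#' (each child on its parents) are fitted so coefficients can later be
#' model-averaged. A model with any failed claim is flagged unevaluable.
#'
#' @param model A [causal_dag()].
#' @param data Data.frame of standardized variables (rownames = species)
#'   containing every DAG vertex; the binary vertex coded 0/1.
#' @param cov A [phylo_cov()] (Brownian scaling; per-fit lambda handled by
#'   the engines).
#' @param binary Name of the binary vertex (`NULL` for all-continuous
#'   DAGs).
#' @param lambda Passed to [fit_pgls()].
#' @param cache Optional environment memoizing fits across models that
#'   share regressions (used by [phylo_path()]).
#' @param model_id Label used in selection tables (defaults to "model").
#' @return An object of class `dsep_fit`: list with `model_id`, `claims`
#'   (data.frame with p-values), `C`, `df`, `p`, `q`, `n`, `CICc`,
#'   `coef_table` (per-edge coefficient, SE, p) and `evaluable`.
#' @export
run_dsep <- function(model, data, cov, binary = NULL, lambda = "ML",
                     cache = new.env(parent = emptyenv()),
                     model_id = NULL) {
  stopifnot(inherits(model, "causal_dag"))
  miss <- setdiff(model$vertices, names(data))
  if (length(miss) > 0L)
    stop("DAG vertices missing from data: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  claims <- basis_set(model, binary)
  k <- nrow(claims)
  pvals <- numeric(k)
  flagged <- character(0)
  if (k > 0L) {
    for (i in seq_len(k)) {
      res <- memo_fit(claims$response[i],
                      c(claims$predictor[i], claims$conditioning[[i]]),
                      data, cov, binary, lambda, cache)
      if (is.null(res$fit) || !res$fit$converged) {
        flagged <- c(flagged, paste0(claims$x[i], " _||_ ", claims$y[i]))
        pvals[i] <- NA_real_
      } else {
        pvals[i] <- res$fit$p_values[[claim_coef_name(res$fit, claims$predictor[i])]]
      }
    }
  }
  claims$p_value <- pvals
  evaluable <- length(flagged) == 0L
  fc <- if (evaluable) fishers_c(pvals) else list(C = NA_real_, df = 2L * k, p = NA_real_)
  q <- model$q
  ic <- if (evaluable) cicc(fc$C, q, n) else NA_real_
  coefs <- path_coefficients(model, data, cov, binary, lambda, cache)
  structure(list(model_id = model_id %||% "model", model = model,
                 claims = claims, k = k, C = fc$C, df = fc$df, p = fc$p,
                 q = q, n = n, CICc = ic, coef_table = coefs,
                 evaluable = evaluable, flagged = flagged),
            class = "dsep_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

claim_coef_name <- function(fit, predictor) {
  nm <- names(fit$coefficients)
  hit <- nm[nm == predictor]
  if (length(hit) == 0L) hit <- grep(predictor, nm, fixed = TRUE, value = TRUE)
  hit[1L]
}

memo_fit <- function(response, predictors, data, cov, binary, lambda, cache) {
  predictors <- unique(predictors)
  key <- paste(response, paste(sort(predictors), collapse = ","), sep = "~")
  if (!is.null(cache[[key]])) return(cache[[key]])
  fml <- stats::reformulate(predictors, response = response)
  fit <- tryCatch(
    withCallingHandlers({
      if (!is.null(binary) && response == binary)
        fit_phylo_logistic(fml, data, cov)
      else
        fit_pgls(fml, data, cov, lambda = lambda)
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  res <- list(fit = fit)
  cache[[key]] <- res
  res
}

# Per-edge path coefficients: one regression of each child on its parents.
path_coefficients <- function(model, data, cov, binary, lambda, cache) {
  children <- unique(model$edges[, 2L])
  rows <- list()
  for (ch in children) {
    pa <- dag_parents(model, ch)
    res <- memo_fit(ch, pa, data, cov, binary, lambda, cache)
    for (v in pa) {
      cn <- if (is.null(res$fit)) NA_character_ else claim_coef_name(res$fit, v)
      rows[[length(rows) + 1L]] <- data.frame(
        from = v, to = ch,
        estimate = if (is.null(res$fit)) NA_real_ else unname(res$fit$coefficients[cn]),
        se = if (is.null(res$fit)) NA_real_ else unname(res$fit$se[cn]),
        p_value = if (is.null(res$fit)) NA_real_ else unname(res$fit$p_values[cn]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(from = character(), to = character(), estimate = numeric(),
                      se = numeric(), p_value = numeric()))
  do.call(rbind, rows)
}

#' @export
print.dsep_fit <- function(x, ...) {
  cat("d-sep fit:", x$model_id, "\n")
  cat(sprintf("  k = %d claims, C = %.3f, df = %d, p = %.4f, q = %d, n = %d, CICc = %.3f\n",
              x$k, x$C, x$df, x$p, x$q, x$n, x$CICc))
  if (!x$evaluable) cat("  UNEVALUABLE; failed claims:",
                        paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' Rank candidate models by CICc
#'
#' Sorts evaluable models by CICc, computes `delta = CICc - min(CICc)`
#' and the CICc weights `omega = exp(-delta/2) / sum(exp(-delta/2))` over
#' all evaluable models. A model is *supported* when `delta <
#' delta_threshold` AND its d-sep p-value is at least `alpha` (its
#' conditional independencies are met). `omega_renorm` additionally gives
#' the weights renormalised over the supported rows only.
#'
#' @param fits List of [run_dsep()] results.
#' @param delta_threshold Support threshold on delta (default 2).
#' @param alpha d-sep rejection level (default 0.05).
#' @return A `dsep_selection` data.frame with one row per evaluable model:
#'   `model`, `k`, `q`, `C`, `p`, `CICc`, `delta`, `omega`,
#'   `omega_renorm`, `supported`. Unevaluable models are listed in the
#'   `dropped` attribute.
#' @export
select_models <- function(fits, delta_threshold = 2, alpha = 0.05) {
  if (inherits(fits, "dsep_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("no model fits supplied")
  ok <- vapply(fits, function(f) isTRUE(f$evaluable), logical(1L))
  if (!any(ok)) stop("no evaluable model fits")
  dropped <- vapply(fits[!ok], `[[`, character(1L), "model_id")
  fits <- fits[ok]
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1L), "model_id"),
    k = vapply(fits, `[[`, integer(1L), "k"),
    q = vapply(fits, `[[`, numeric(1L), "q"),
    C = vapply(fits, `[[`, numeric(1L), "C"),
    p = vapply(fits, `[[`, numeric(1L), "p"),
    CICc = vapply(fits, `[[`, numeric(1L), "CICc"),
    stringsAsFactors = FALSE)
  o <- order(tab$CICc)
  tab <- tab[o, , drop = FALSE]
  fits <- fits[o]
  tab$delta <- tab$CICc - tab$CICc[1L]
  w <- exp(-tab$delta / 2)
  tab$omega <- w / sum(w)
  tab$supported <- tab$delta < delta_threshold & tab$p >= alpha
  tab$omega_renorm <- ifelse(tab$supported,
                             tab$omega / sum(tab$omega[tab$supported]), NA_real_)
  rownames(tab) <- NULL
  structure(tab, class = c("dsep_selection", "data.frame"),
            fits = fits, dropped = dropped,
            delta_threshold = delta_threshold, alpha = alpha)
}

#' @export
print.dsep_selection <- function(x, digits = 3, ...) {
  cat("Model selection by CICc (", sum(x$supported), " of ", nrow(x),
      " models supported)\n\n", sep = "")
  df <- as.data.frame(x)
  df$C <- round(df$C, 2); df$p <- round(df$p, 3)
  df$CICc <- round(df$CICc, 2); df$delta <- round(df$delta, 2)
  df$omega <- round(df$omega, 3); df$omega_renorm <- round(df$omega_renorm, 3)
  print(df, row.names = FALSE)
  dr <- attr(x, "dropped")
  if (length(dr) > 0L) cat("\nunevaluable models:", paste(dr, collapse = ", "), "\n")
  invisible(x)
}

#' Conditional model averaging of path coefficients
#'
#' For every edge present in at least one supported model, the averaged
#' standardized coefficient is the weighted mean of that edge's
#' coefficient over the supported models *containing* the edge, with the
#' CICc weights renormalised over those models (conditional averaging).
#' The averaged SE uses the unconditional-variance estimator, which folds
#' the between-model spread into the within-model SEs:
#' `se = sum_m w_m * sqrt(se_m^2 + (b_m - b_avg)^2)`.
#'
#' @param selection A [select_models()] result (with its `fits`
#'   attribute, as produced via [phylo_path()] or [run_dsep()]).
#' @return An `averaged_paths` data.frame: `from`, `to`, `estimate`, `se`,
#'   `n_models` (supported models containing the edge), plus the
#'   contributing model ids in the `contributing` list-column.
#' @export
average_paths <- function(selection) {
  stopifnot(inherits(selection, "dsep_selection"))
  fits <- attr(selection, "fits")
  sup <- which(selection$supported)
  if (length(sup) == 0L) stop("no supported models to average")
  omega <- selection$omega[sup]
  ctabs <- lapply(fits[sup], `[[`, "coef_table")
  edges <- unique(do.call(rbind, lapply(ctabs, function(d) d[, c("from", "to")])))
  rows <- list()
  for (r in seq_len(nrow(edges))) {
    e <- edges[r, ]
    est <- se <- w <- numeric(0)
    contrib <- character(0)
    for (m in seq_along(ctabs)) {
      hit <- ctabs[[m]]$from == e$from & ctabs[[m]]$to == e$to
      if (any(hit)) {
        est <- c(est, ctabs[[m]]$estimate[hit])
        se <- c(se, ctabs[[m]]$se[hit])
        w <- c(w, omega[m])
        contrib <- c(contrib, selection$model[sup[m]])
      }
    }
    w <- w / sum(w)
    b <- sum(w * est)
    rows[[r]] <- list(from = e$from, to = e$to, estimate = b,
                      se = sum(w * sqrt(se^2 + (est - b)^2)),
                      n_models = length(contrib), contributing = contrib)
  }
  out <- data.frame(from = vapply(rows, `[[`, character(1L), "from"),
                    to = vapply(rows, `[[`, character(1L), "to"),
                    estimate = vapply(rows, `[[`, numeric(1L), "estimate"),
                    se = vapply(rows, `[[`, numeric(1L), "se"),
                    n_models = vapply(rows, `[[`, numeric(1L), "n_models"),
                    stringsAsFactors = FALSE)
  out$contributing <- lapply(rows, `[[`, "contributing")
  structure(out, class = c("averaged_paths", "data.frame"))
}

#' @export
print.averaged_paths <- function(x, digits = 3, ...) {
  cat("Model-averaged standardized path coefficients\n")
  df <- as.data.frame(x)[, c("from", "to", "estimate", "se", "n_models")]
  df$estimate <- round(df$estimate, digits)
  df$se <- round(df$se, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Phylogenetic path analysis
#'
#' The package's central fitting function. Enumerates the candidate
#' causal models (trait-only DAG plus every subset of the candidate
#' direct links to the binary outcome), runs the d-separation test of
#' each model on the data with phylogenetic regressions, ranks models by
#' CICc and computes CICc weights. Fits are memoized across models, which
#' share most of their regressions. Use [average_paths()] on the result
#' (or `coef()`) for the conditionally model-averaged coefficients.
#'
#' @param trait_only A [causal_dag()] over the trait variables.
#' @param candidate_links Character vector of traits that may directly
#'   cause the outcome.
#' @param data Standardized trait data.frame (rownames = species) with the
#'   0/1 outcome column.
#' @param tree A `phylo` object, or a precomputed [phylo_cov()].
#' @param outcome Name of the binary outcome column (default `"urban"`).
#' @param lambda Pagel's lambda mode for the Gaussian engine
#'   (default `"ML"`).
#' @param delta_threshold,alpha Support rules passed to [select_models()].
#' @return An object of class `phylo_path`: list with `selection` (a
#'   [select_models()] table), `fits`, `models`, `average` (the
#'   [average_paths()] result, `NULL` when nothing is supported), `n`.
#' @examples
#' \donttest{
#' sim <- simulate_traits(simulate_yule_tree(60, seed = 1),
#'                        example_simulation_config(n_species = 60), seed = 2)
#' pp <- phylo_path(example_trait_dag(), c("DD", "LS"), sim$table, sim$tree)
#' pp
#' }
#' @export
phylo_path <- function(trait_only, candidate_links, data, tree,
                       outcome = "urban", lambda = "ML",
                       delta_threshold = 2, alpha = 0.05) {
  cov <- if (inherits(tree, "phylo_cov")) tree else phylo_cov(tree, lambda = 1)
  models <- enumerate_models(trait_only, candidate_links, outcome)
  cache <- new.env(parent = emptyenv())
  fits <- vector("list", length(models))
  for (i in seq_along(models)) {
    fits[[i]] <- run_dsep(models[[i]], data, cov, binary = outcome,
                          lambda = lambda, cache = cache,
                          model_id = names(models)[i])
  }
  sel <- select_models(fits, delta_threshold = delta_threshold, alpha = alpha)
  avg <- if (any(sel$supported)) average_paths(sel) else NULL
  structure(list(selection = sel, fits = fits, models = models,
                 average = avg, n = nrow(data), outcome = outcome,
                 call = match.call()),
            class = "phylo_path")
}

#' @export
print.phylo_path <- function(x, ...) {
  cat("Phylogenetic path analysis: ", length(x$models), " candidate models, n = ",
      x$n, " species\n\n", sep = "")
  print(x$selection)
  invisible(x)
}

#' @export
summary.phylo_path <- function(object, ...) {
  cat("Phylogenetic path analysis\n")
  cat("call: "); print(object$call)
  print(object$selection)
  if (!is.null(object$average)) {
    cat("\n")
    print(object$average)
  } else cat("\nNo supported model; no averaged coefficients.\n")
  invisible(object)
}

#' @export
coef.phylo_path <- function(object, ...) {
  if (is.null(object$average)) stop("no supported models; nothing to average")
  stats::setNames(object$average$estimate,
                  paste(object$average$from, object$average$to, sep = "->"))
}

#' @export
plot.phylo_path <- function(x, ...) {
  sel <- x$selection
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(sel$omega, names.arg = sel$model, las = 2,
                          ylab = "CICc weight", cex.names = 0.7,
                          col = ifelse(sel$supported, "steelblue", "grey80"), ...)
  graphics::abline(h = 0)
  invisible(bp)
}
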