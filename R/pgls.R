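#' Phylogenetic generalized least squares
#'
#' Fits `y = X b + e` with `Var(e) = sigma2 * V(lambda)`, where
#' `V(lambda)` is the phylogenetic covariance with Pagel's lambda applied
#' to the off-diagonal entries. `lambda` is either fixed or estimated by
#' maximizing the restricted likelihood over \[0, 1\]. Coefficients are
#' tested with t statistics on `n - p` degrees of freedom (`p` columns in
#' the design including the intercept). Estimates are invariant to a
#' global rescaling of branch lengths.
#'
#' @param formula Model formula.
#' @param data Data.frame whose rownames are species labels matching the
#'   covariance (rows are reordered to the covariance's species order when
#'   they match by name; otherwise positional order is assumed).
#' @param cov A [phylo_cov()] object, a `phylo` tree, or a covariance
#'   matrix (its lambda, if any, is treated as a fixed pre-scaling;
#'   `lambda` below acts on top of the Brownian part).
#' @param lambda `"ML"` (default) to estimate Pagel's lambda by REML, or a
#'   fixed number in \[0, 1\].
#' @return An object of class `pgls` with the usual accessors (`coef`,
#'   `vcov`, `summary`, `residuals`, `fitted`, `predict`, `logLik`).
#' @examples
#' tr <- ape::rcoal(20)
#' d <- data.frame(x = rnorm(20), row.names = tr$tip.label)
#' d$y <- d$x + rnorm(20)
#' fit_pgls(y ~ x, d, phylo_cov(tr), lambda = 1)
#' @export
fit_pgls <- function(formula, data, cov, lambda = "ML") {
  C <- align_cov(cov, data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(mf), mf)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("too few observations: n = ", n, ", p = ", p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  dec <- gls_decomp(C, cov_cache(cov))
  if (identical(lambda, "ML") || identical(lambda, "ml")) {
    opt <- stats::optimize(function(l) gls_neg2_reml(l, y, X, dec),
                           interval = c(0, 1), tol = 1e-8)
    # the optimum can sit on a boundary that optimize never probes exactly
    cand <- c(opt$minimum, 0, 1)
    vals <- c(opt$objective, gls_neg2_reml(0, y, X, dec),
              gls_neg2_reml(1, y, X, dec))
    lam <- cand[which.min(vals)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be 'ML' or a number in [0, 1]")
    lam <- lambda
  }
  g <- gls_solve(lam, y, X, dec)
  df <- n - p
  sigma2 <- g$rss / df
  covb <- sigma2 * g$XtVinvX_inv
  se <- sqrt(diag(covb))
  tstat <- g$beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  loglik <- -0.5 * (df * (log(2 * pi) + log(sigma2) + 1) +
                      g$logdetV + g$logdetXtVX)
  fitted <- drop(X %*% g$beta)
  structure(list(
    coefficients = stats::setNames(drop(g$beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    statistic = stats::setNames(tstat, colnames(X)),
    p_values = stats::setNames(pval, colnames(X)),
    df.residual = df, sigma2 = sigma2, lambda = lam,
    vcov = structure(covb, dimnames = list(colnames(X), colnames(X))),
    logLik = loglik, n = n, fitted.values = fitted,
    residuals = y - fitted, formula = formula,
    terms = stats::terms(mf), converged = TRUE,
    call = match.call()), class = "pgls")
}

# Align covariance rows/cols to the data rows; returns plain matrix.
align_cov <- function(cov, data) {
  C <- as_cov_matrix(cov)
  rn <- rownames(data)
  if (!is.null(rn) && !is.null(rownames(C)) && all(rn %in% rownames(C))) {
    C <- C[rn, rn, drop = FALSE]
  } else if (nrow(C) != nrow(data)) {
    stop("covariance (", nrow(C), ") and data (", nrow(data),
         ") sizes differ and species names do not match")
  }
  C
}

# Spectral machinery shared across lambda evaluations. For trees with a
# constant diagonal (ultrametric) V(lambda) shares C's eigenvectors, so a
# single decomposition serves every lambda. Otherwise V is built and
# factorized per lambda.
gls_decomp <- function(C, cache = new.env(parent = emptyenv())) {
  key <- paste0("d", nrow(C), "_", signif(sum(C), 12))
  if (!is.null(cache[[key]])) return(cache[[key]])
  d <- diag(C)
  const <- max(d) - min(d) < 1e-10 * max(d)
  dec <- if (const) {
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(e$values))
      stop("phylogenetic covariance is not positive semidefinite")
    list(type = "eigen", U = e$vectors, ev = e$values, height = mean(d))
  } else {
    list(type = "chol", C = C, D = d)
  }
  cache[[key]] <- dec
  dec
}

# beta-hat, RSS and determinants for V(lambda); eigen route rotates once.
gls_solve <- function(lambda, y, X, dec) {
  if (dec$type == "eigen") {
    v <- lambda * dec$ev + (1 - lambda) * dec$height
    v <- pmax(v, 1e-12 * dec$height)
    yt <- crossprod(dec$U, y)
    Xt <- crossprod(dec$U, X)
    w <- 1 / v
    A <- crossprod(Xt, Xt * w)
    Ainv <- chol2inv(chol(A))
    beta <- Ainv %*% crossprod(Xt, yt * w)
    r <- yt - Xt %*% beta
    beta <- drop(beta)
    list(beta = beta, rss = sum(w * r^2), logdetV = sum(log(v)),
         logdetXtVX = determinant(A, logarithm = TRUE)$modulus[1L],
         XtVinvX_inv = Ainv)
  } else {
    V <- lambda * dec$C
    diag(V) <- dec$D
    U <- tryCatch(chol(V), error = function(e) {
      chol(V + diag(1e-10 * mean(dec$D), nrow(V)))
    })
    yt <- backsolve(U, y, transpose = TRUE)
    Xt <- backsolve(U, X, transpose = TRUE)
    A <- crossprod(Xt)
    Ainv <- chol2inv(chol(A))
    beta <- Ainv %*% crossprod(Xt, yt)
    r <- yt - Xt %*% beta
    beta <- drop(beta)
    list(beta = beta, rss = sum(r^2), logdetV = 2 * sum(log(diag(U))),
         logdetXtVX = determinant(A, logarithm = TRUE)$modulus[1L],
         XtVinvX_inv = Ainv)
  }
}

gls_neg2_reml <- function(lambda, y, X, dec) {
  g <- gls_solve(lambda, y, X, dec)
  df <- length(y) - ncol(X)
  df * log(g$rss / df) + g$logdetV + g$logdetXtVX
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS, n =", x$n, " lambda =", format(x$lambda, digits = 4), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$statistic, `Pr(>|t|)` = object$p_values)
  structure(list(call = object$call, coefficients = tab,
                 lambda = object$lambda, sigma2 = object$sigma2,
                 df.residual = object$df.residual, logLik = object$logLik,
                 n = object$n),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic generalized least squares\n")
  cat("n =", x$n, "  Pagel's lambda =", format(x$lambda, digits = 4),
      "  sigma2 =", format(x$sigma2, digits = 4), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nRestricted log-likelihood:", format(x$logLik, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  drop(X %*% object$coefficients)
}
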