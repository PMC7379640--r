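#' Phylogenetic logistic regression (penalized quasi-likelihood)
#'
#' Logistic regression for a binary species trait in which phylogenetic
#' correlation enters on the latent (logit) scale: the liability is
#' `eta = X b + u` with `u ~ N(0, s * Cstar)`, `Cstar` the phylogenetic
#' correlation matrix. The latent variance `s` ("signal") is estimated by
#' restricted likelihood on the working model inside an iteratively
#' reweighted GLS loop; a Firth/Jeffreys penalty keeps estimates finite
#' under complete separation and reduces the small-sample bias that rare
#' (zero-inflated) outcomes induce. With a star phylogeny `Cstar` is
#' diagonal, the signal is unidentifiable from off-diagonal covariance and
#' is fixed at 0, and the fit reduces exactly to ordinary Firth-penalized
#' logistic regression. Coefficients are tested with Wald z statistics.
#'
#' @param formula Model formula; the response must be 0/1 with both
#'   classes present.
#' @param data Data.frame, rownames matching the covariance species.
#' @param cov A [phylo_cov()], `phylo` tree, or covariance matrix.
#' @param penalized Apply the Firth penalty (default `TRUE`).
#' @param signal `"reml"` (default) to estimate the latent-scale variance,
#'   or a fixed non-negative number.
#' @param s_max Upper bound of the signal search (default 10).
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   coefficients. Non-convergence is flagged (`converged = FALSE`), never
#'   returned as silent `NaN`.
#' @return An object of class `phylo_logistic` with `coef`, `vcov`,
#'   `summary`, `fitted`, `predict` methods; `signal` holds the estimated
#'   latent variance.
#' @export
fit_phylo_logistic <- function(formula, data, cov, penalized = TRUE,
                               signal = "reml", s_max = 10,
                               max_iter = 200, tol = 1e-8) {
  C <- align_cov(cov, data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("response has a single class; cannot fit")
  X <- stats::model.matrix(stats::terms(mf), mf)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1L) stop("too few observations: n = ", n, ", p = ", p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  Cstar <- stats::cov2cor(C)
  has_structure <- max(abs(Cstar[upper.tri(Cstar)])) > 1e-12
  est_signal <- identical(signal, "reml")
  s <- if (est_signal) 0 else {
    if (!is.numeric(signal) || signal < 0) stop("signal must be 'reml' or >= 0")
    signal
  }
  if (!has_structure) {
    est_signal <- FALSE
    if (s > 0) warning("covariance is diagonal; signal fixed at 0")
    s <- 0
  }

  beta0 <- c(stats::qlogis((sum(y) + 0.5) / (n + 1)), rep(0, p - 1L))
  base <- plogit_irls(beta0, 0, y, X, Cstar, penalized, max_iter, tol)
  if (est_signal) {
    # profile the latent variance on the working-model restricted
    # likelihood; an s whose inner IRLS does not converge is excluded
    profile_s <- function(ss) {
      inn <- plogit_irls(base$beta, ss, y, X, Cstar, penalized, max_iter, tol)
      if (!inn$converged) return(Inf)
      plogit_neg2_reml(ss, inn$z, inn$W, X, Cstar)
    }
    at0 <- if (base$converged)
      plogit_neg2_reml(0, base$z, base$W, X, Cstar) else Inf
    opt <- stats::optimize(profile_s, interval = c(0, s_max), tol = 1e-3)
    s <- if (at0 <= opt$objective) 0 else opt$minimum
  }
  fin <- if (s == 0) base else
    plogit_irls(base$beta, s, y, X, Cstar, penalized, max_iter, tol)
  beta <- fin$beta
  converged <- fin$converged
  covb <- fin$Ainv
  se <- sqrt(diag(covb))
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  if (penalized) ll <- ll + 0.5 * determinant(fin$A, logarithm = TRUE)$modulus[1L]
  if (!converged)
    warning("phylogenetic logistic fit did not converge; estimates are flagged")
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    statistic = stats::setNames(drop(zstat), colnames(X)),
    p_values = stats::setNames(drop(pval), colnames(X)),
    signal = s, vcov = structure(covb, dimnames = list(colnames(X), colnames(X))),
    logLik = ll, n = n, fitted.values = mu, linear.predictors = eta,
    residuals = y - mu, penalized = penalized, converged = converged,
    formula = formula, terms = stats::terms(mf), call = match.call()),
    class = "phylo_logistic")
}

# One Firth-IRLS pass at fixed latent variance s. Returns the working
# response and weights of the last iteration for the REML signal update.
plogit_irls <- function(beta, s, y, X, Cstar, penalized, max_iter, tol) {
  n <- nrow(X)
  converged <- FALSE
  z <- NULL; W <- NULL; A <- NULL; Ainv <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    if (s > 0) {
      Vw <- s * Cstar
      diag(Vw) <- diag(Vw) + 1 / W
      U <- chol(Vw)
      MX <- backsolve(U, backsolve(U, X, transpose = TRUE))
    } else {
      MX <- X * W
    }
    A <- crossprod(X, MX)
    Ainv <- chol2inv(chol(A))
    adj <- if (penalized) {
      h <- rowSums((X %*% Ainv) * MX) # leverages of the working GLS fit
      h * (0.5 - mu)
    } else 0
    z <- eta + (y - mu + adj) / W
    beta_new <- drop(Ainv %*% crossprod(MX, z))
    # damp late iterations: plain IRLS can cycle when the latent variance
    # is large and the outcome rare
    damp <- if (iter > 60L) 0.25 else if (iter > 25L) 0.5 else 1
    beta_new <- beta + damp * (beta_new - beta)
    # trust region: standardized predictors make |beta| > 30 meaningless,
    # so runaway working steps are truncated instead of propagated
    beta_new <- pmin(pmax(beta_new, -30), 30)
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, z = z, W = W, A = A, Ainv = Ainv, converged = converged)
}

# -2 * restricted log-likelihood of the working model z = X b + u + e,
# Var = s * Cstar + diag(1/W), with W held fixed.
plogit_neg2_reml <- function(s, z, W, X, Cstar) {
  Vw <- s * Cstar
  diag(Vw) <- diag(Vw) + 1 / W
  U <- tryCatch(chol(Vw), error = function(e) NULL)
  if (is.null(U)) return(Inf)
  zt <- backsolve(U, z, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  A <- crossprod(Xt)
  Ainv <- chol2inv(chol(A))
  r <- zt - Xt %*% (Ainv %*% crossprod(Xt, zt))
  2 * sum(log(diag(U))) + determinant(A, logarithm = TRUE)$modulus[1L] + sum(r^2)
}

#' @export
print.phylo_logistic <- function(x, ...) {
  cat("Phylogenetic logistic regression, n =", x$n,
      " signal =", format(x$signal, digits = 4),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.phylo_logistic <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$statistic, `Pr(>|z|)` = object$p_values)
  structure(list(call = object$call, coefficients = tab,
                 signal = object$signal, penalized = object$penalized,
                 converged = object$converged, n = object$n),
            class = "summary.phylo_logistic")
}

#' @export
print.summary.phylo_logistic <- function(x, ...) {
  cat("Phylogenetic logistic regression",
      if (x$penalized) "(Firth-penalized)", "\n")
  cat("n =", x$n, "  latent signal =", format(x$signal, digits = 4), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.phylo_logistic <- function(object, ...) object$coefficients

#' @export
vcov.phylo_logistic <- function(object, ...) object$vcov

#' @export
nobs.phylo_logistic <- function(object, ...) object$n

#' @export
fitted.phylo_logistic <- function(object, ...) object$fitted.values

#' @export
residuals.phylo_logistic <- function(object, ...) object$residuals

#' @export
predict.phylo_logistic <- function(object, newdata = NULL,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$linear.predictors else {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}
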