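#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around iteratively reweighted least squares
#' ([stats::glm.fit()]) used by every association routine in the package.
#' The design matrix is checked for full column rank up front (naming the
#' collinear columns on failure), convergence is tightened to a relative
#' deviance change below 1e-10 within 100 iterations, and standard errors
#' come from the observed information at the MLE. Fits that fail to
#' converge or show signs of separation (exploding coefficients or
#' standard errors) are returned with `converged = FALSE` so callers can
#' exclude them downstream rather than silently report them.
#'
#' @param X Numeric design matrix including the intercept column.
#' @param y 0/1 response with both classes present.
#' @return A list with `beta`, `se` (named per column of `X`),
#'   `converged`, `loglik`, and `n`.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  if (length(unique(y)) < 2L) abort("`y` must contain both classes.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(
      sprintf(
        "design matrix is rank deficient; collinear column(s): %s",
        paste(dropped, collapse = ", ")
      ),
      class = "haplofine_rank_deficient"
    )
  }
  fit <- suppressWarnings(glm.fit(
    x = X, y = y, family = binomial(),
    control = glm.control(epsilon = 1e-10, maxit = 100)
  ))
  beta <- coef(fit)
  w <- fit$weights
  info <- crossprod(X, X * w)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, ncol(X)) else sqrt(diag(cov))
  names(se) <- colnames(X)
  converged <- isTRUE(fit$converged) &&
    all(is.finite(se)) && max(abs(beta)) < 50 && max(se) < 1e3
  ll <- -fit$deviance / 2
  list(beta = beta, se = se, converged = converged, loglik = ll, n = length(y))
}

# Build the covariate part of a design matrix from the phenotype tibble.
# Constant columns carry no information and would only break the rank
# check (e.g. a batch flag absent from the sample), so they are dropped.
covariate_matrix <- function(pheno, covariates) {
  covariates <- intersect(covariates, names(pheno))
  if (!length(covariates)) {
    return(matrix(numeric(0), nrow = nrow(pheno), ncol = 0))
  }
  m <- as.matrix(pheno[, covariates, drop = FALSE])
  keep <- apply(m, 2L, function(x) length(unique(x)) > 1L)
  m[, keep, drop = FALSE]
}
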