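#' Recode 0/1 parental genotypes to -1/+1
#'
#' Standard centered coding for a balanced biparental DH population, used
#' for the GBLUP benchmark. Predictions are invariant to affine recoding up
#' to the intercept.
#'
#' @param genotypes 0/1 matrix.
#' @return Matrix with entries in `{-1, 1}`.
#' @export
code_markers <- function(genotypes) {
  2 * as.matrix(genotypes) - 1
}

#' Fit the GBLUP benchmark model
#'
#' Ridge-type genomic mixed model `y = beta0 + Z u + e` with marker effects
#' `u ~ N(0, vg I)` and residuals `e ~ N(0, ve I)`. Variance components are
#' estimated by REML through the one-dimensional spectral profile
#' likelihood: after projecting out the intercept, the likelihood is
#' profiled over the shrinkage ratio `lambda = ve / vg` using the
#' eigendecomposition of `Z Z'`, then optimised on the log scale. Marker
#' effects are recovered in the equivalent kernel form
#' `u = Z' (Z Z' + lambda I)^{-1} (y - beta0)` with the generalized
#' least-squares intercept, which also handles rank-degenerate `Z`.
#'
#' @param y Phenotype vector (length `N >= 3`).
#' @param Z `N x M` marker matrix (any centered coding; see
#'   [code_markers()]).
#' @param lambda Optional fixed shrinkage ratio; when supplied the REML
#'   step is skipped (used for cross-checking against direct solvers).
#' @param tol Optimiser tolerance on `log(lambda)`.
#' @return Object of class `gblup_fit`: `beta0`, `u`, `vg`, `ve`,
#'   `lambda`, `fitted`.
#' @export
fit_gblup <- function(y, Z, lambda = NULL, tol = 1e-8) {
  Z <- as.matrix(Z)
  n <- length(y)
  stopifnot(n == nrow(Z), n >= 3, ncol(Z) >= 1)
  check_finite(y, "y")

  if (stats::var(y) == 0) {
    fit <- list(beta0 = y[1], u = rep(0, ncol(Z)), vg = 0, ve = 0,
                lambda = Inf, fitted = rep(y[1], n))
    return(structure(fit, class = "gblup_fit"))
  }

  K <- tcrossprod(Z)
  if (is.null(lambda)) {
    # spectral profile REML (EMMA-style), intercept projected out.
    # Decompose S (K + I) S rather than S K S: the +I offset makes the
    # intercept direction the unique zero eigenvalue, so it cannot mix
    # with null-space directions of a rank-deficient K.
    S <- diag(n) - matrix(1 / n, n, n)
    eig <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
    m <- n - 1L
    xi <- pmax(eig$values[seq_len(m)] - 1, 0)
    eta <- drop(crossprod(eig$vectors[, seq_len(m), drop = FALSE], y))
    restricted_ll <- function(log_delta) {
      delta <- exp(log_delta)
      denom <- xi + delta
      rss <- sum(eta^2 / denom)
      -0.5 * (m * log(rss) + sum(log(denom)))
    }
    grid <- seq(-25, 25, length.out = 201)
    ll <- vapply(grid, restricted_ll, numeric(1))
    best <- grid[which.max(ll)]
    opt <- stats::optimize(restricted_ll, c(best - 1, best + 1),
                           maximum = TRUE, tol = tol)
    lambda <- exp(opt$maximum)
    vg <- sum(eta^2 / (xi + lambda)) / m
    ve <- lambda * vg
  } else {
    vg <- NA_real_
    ve <- NA_real_
  }

  eigK <- eigen(K, symmetric = TRUE)
  d <- pmax(eigK$values, 0)
  Ut_y <- drop(crossprod(eigK$vectors, y))
  Ut_1 <- drop(crossprod(eigK$vectors, rep(1, n)))
  w <- 1 / (d + lambda)
  beta0 <- sum(Ut_1 * w * Ut_y) / sum(Ut_1 * w * Ut_1)
  resid_rot <- w * (Ut_y - Ut_1 * beta0)
  u <- drop(crossprod(Z, eigK$vectors %*% resid_rot))
  fitted <- beta0 + drop(Z %*% u)
  structure(list(beta0 = beta0, u = u, vg = vg, ve = ve, lambda = lambda,
                 fitted = fitted),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit> %d marker effects, lambda %.4g (vg %.4g, ve %.4g)\n",
    length(x$u), x$lambda, x$vg, x$ve))
  invisible(x)
}

#' Predict yields from a GBLUP fit
#'
#' Predictions are `beta0 + Z_new u`. GBLUP carries no environmental input,
#' so predictions are identical for every target environment.
#'
#' @param fit A [fit_gblup()] object.
#' @param Z_new Marker matrix with the same column count as the training
#'   matrix.
#' @return Predicted yield vector.
#' @export
predict_gblup <- function(fit, Z_new) {
  stopifnot(inherits(fit, "gblup_fit"))
  Z_new <- as.matrix(Z_new)
  if (ncol(Z_new) != length(fit$u))
    stop("dimension mismatch: fit has ", length(fit$u), " marker effects",
         call. = FALSE)
  drop(fit$beta0 + Z_new %*% fit$u)
}
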