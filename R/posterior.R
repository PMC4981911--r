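#' Draw from the conjugate posterior of a bivariate-response regression
#'
#' For complete bivariate responses `y` (n x 2) and design `X` (n x p), under
#' the noninformative Jeffreys-style prior (flat on coefficients,
#' `|Sigma|^-(d+1)/2` on the residual covariance), the posterior is the
#' standard normal-inverse-Wishart form: `Sigma | y ~ IW(n - p, S)` with `S`
#' the residual cross-product matrix, and the coefficient matrix is matrix
#' normal `MN(Bhat, (X'X)^-1, Sigma)` given `Sigma`. One joint draw is
#' returned; this is the Bayesian step that makes the single-level and
#' fixed-effects imputations proper.
#'
#' @param y Numeric matrix of responses, `n` rows, 2 columns, no missing
#'   values.
#' @param X Numeric design matrix with linearly independent columns.
#' @return A list with `coef` (p x 2 coefficient draw) and `resid_cov`
#'   (2 x 2 residual covariance draw).
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(200), 100, 2)
#' draw_regression_posterior(y, cbind(1, rnorm(100)))
#' @export
draw_regression_posterior <- function(y, X) {
  y <- as.matrix(y)
  X <- as.matrix(X)
  if (ncol(y) != 2 || anyNA(y)) abort("`y` must be a complete n x 2 matrix")
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(y) != n) abort("`y` and `X` must have the same number of rows")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    if (is.null(bad)) bad <- as.character(qx$pivot[(qx$rank + 1):p])
    abort(sprintf("design is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (n <= p + 2) {
    abort(sprintf(
      "insufficient data for a proper posterior: n = %d rows but p + 2 = %d",
      n, p + 2))
  }
  bhat <- qr.coef(qx, y)
  res <- y - X %*% bhat
  S <- crossprod(res)
  df <- n - p
  # Sigma ~ IW(df, S): draw the precision from Wishart(df, S^-1) and invert
  sigma <- chol2inv(chol(rWishart(1, df, chol2inv(chol(S)))[, , 1]))
  xtxi <- chol2inv(qr.R(qx)[seq_len(p), seq_len(p), drop = FALSE])
  coef <- bhat + t(chol(xtxi)) %*% matrix(rnorm(2 * p), p, 2) %*% chol(sigma)
  dimnames(coef) <- dimnames(bhat)
  list(coef = coef, resid_cov = sigma)
}

# Fill the missing entries of y (flagged by r == 1) given per-row means `mu`
# and residual covariance `sigma`: joint bivariate draw when both outcomes are
# missing, conditional normal given the observed co-outcome when only one is.
fill_bivariate <- function(y, r, mu, sigma) {
  both <- r[, 1] == 1L & r[, 2] == 1L
  only1 <- r[, 1] == 1L & r[, 2] == 0L
  only2 <- r[, 1] == 0L & r[, 2] == 1L
  if (any(both)) {
    L <- t(chol(sigma))
    z <- matrix(rnorm(2 * sum(both)), 2)
    y[both, ] <- mu[both, , drop = FALSE] + t(L %*% z)
  }
  if (any(only1)) {
    slope <- sigma[1, 2] / sigma[2, 2]
    csd <- sqrt(sigma[1, 1] - sigma[1, 2]^2 / sigma[2, 2])
    y[only1, 1] <- mu[only1, 1] + slope * (y[only1, 2] - mu[only1, 2]) +
      csd * rnorm(sum(only1))
  }
  if (any(only2)) {
    slope <- sigma[1, 2] / sigma[1, 1]
    csd <- sqrt(sigma[2, 2] - sigma[1, 2]^2 / sigma[1, 1])
    y[only2, 2] <- mu[only2, 2] + slope * (y[only2, 1] - mu[only2, 1]) +
      csd * rnorm(sum(only2))
  }
  y
}

# Assemble the M completed copies into the long stacked format used by all
# engines: one tibble with an `.imp` index, plus attributes recording the
# engine, M and the source data.
new_imputed_stack <- function(copies, source, method) {
  M <- length(copies)
  out <- dplyr::bind_rows(copies, .id = ".imp")
  out$.imp <- as.integer(out$.imp)
  out <- out[, c(".imp", trial_columns)]
  class(out) <- c("crt_imputed", class(out))
  attr(out, "method") <- method
  attr(out, "M") <- M
  attr(out, "source") <- source
  out
}

#' @export
print.crt_imputed <- function(x, ...) {
  cat(sprintf("<%s imputation stack: M = %d completed copies of %d records>\n",
              toupper(attr(x, "method")), attr(x, "M"),
              nrow(x) / attr(x, "M")))
  NextMethod()
}

#' Extract the completed datasets from an imputation stack
#'
#' @param stack A `crt_imputed` object from [impute_smi()], [impute_fmi()] or
#'   [impute_mmi()].
#' @return A list of `M` complete trial tibbles.
#' @export
imputed_sets <- function(stack) {
  stopifnot(inherits(stack, "crt_imputed"))
  out <- split(stack[trial_columns], stack$.imp)
  names(out) <- NULL
  lapply(out, function(d) {
    d$r1 <- 0L
    d$r2 <- 0L
    d
  })
}
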