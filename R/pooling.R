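#' Pool estimates across imputations by Rubin's rules
#'
#' For each treatment effect: the pooled point estimate is the mean of the
#' per-imputation estimates, the within-imputation variance `W` is the mean
#' of the squared standard errors, the between-imputation variance `B` is the
#' sample variance (denominator `M - 1`) of the estimates, and the total
#' variance is `T = W + (1 + 1/M) B`. The full 2 x 2 pooled covariance of
#' `(beta1, beta2)` (needed for the incremental net benefit) is kept as an
#' attribute. Confidence intervals use the normal distribution; see
#' [make_ci()].
#'
#' @param fits A list of `M >= 2` [fit_bivariate_mixed()] results; fits
#'   flagged as non-converged are dropped with a warning.
#' @param level Confidence level for the normal intervals.
#' @return A `crt_pooled` tibble with one row per treatment effect
#'   (`estimate`, `within`, `between`, `total`, `std.error`, `conf.low`,
#'   `conf.high`, `m`) and attributes `vcov_total`, `vcov_within`,
#'   `vcov_between`, `level`.
#' @examples
#' sc <- scenario(J = 6, sizes = fixed_sizes(15),
#'                mechanism = mar_mechanism("both", eta = 1))
#' d <- apply_missingness(generate_trial(sc, seed = 1), sc$mechanism, seed = 2)
#' stack <- impute_smi(d, M = 5, seed = 3)
#' rubin_pool(lapply(imputed_sets(stack), fit_bivariate_mixed))
#' @export
rubin_pool <- function(fits, level = 0.95) {
  if (!is.list(fits) || !all(vapply(fits, inherits, logical(1), "crt_bvmm"))) {
    abort("`fits` must be a list of crt_bvmm fits")
  }
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!conv)) {
    warn(sprintf("dropping %d non-converged fit(s) before pooling", sum(!conv)))
    fits <- fits[conv]
  }
  M <- length(fits)
  if (M < 2) {
    abort("Rubin's rules need at least 2 (converged) fits: between-imputation variance is undefined")
  }
  est <- t(vapply(fits, function(f) f$beta, numeric(2)))
  qbar <- colMeans(est)
  w_mat <- Reduce(`+`, lapply(fits, function(f) f$vcov_treat)) / M
  b_mat <- crossprod(sweep(est, 2, qbar)) / (M - 1)
  t_mat <- w_mat + (1 + 1 / M) * b_mat

  out <- tibble::tibble(
    term = c("beta1", "beta2"),
    estimate = unname(qbar),
    within = unname(diag(w_mat)),
    between = unname(diag(b_mat)),
    total = unname(diag(t_mat)),
    std.error = unname(sqrt(diag(t_mat))),
    m = M
  )
  class(out) <- c("crt_pooled", class(out))
  attr(out, "vcov_total") <- t_mat
  attr(out, "vcov_within") <- w_mat
  attr(out, "vcov_between") <- b_mat
  make_ci(out, level)
}

#' Normal confidence intervals for pooled estimates
#'
#' Adds (or recomputes) `conf.low`/`conf.high` as
#' `estimate +/- z * sqrt(total)`, the normal-approximation interval used
#' throughout (no small-sample multiple-imputation degrees of freedom).
#'
#' @param pooled A `crt_pooled` tibble (or any data frame with `estimate` and
#'   `total` columns).
#' @param level Confidence level in (0, 1).
#' @return The input with `conf.low`/`conf.high` set and the level recorded.
#' @export
make_ci <- function(pooled, level = 0.95) {
  if (!is.data.frame(pooled) || !all(c("estimate", "total") %in% names(pooled))) {
    abort("`pooled` must be a data frame with `estimate` and `total` columns")
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1)")
  }
  z <- z_crit(level)
  half <- z * sqrt(pooled$total)
  pooled$conf.low <- pooled$estimate - half
  pooled$conf.high <- pooled$estimate + half
  attr(pooled, "level") <- level
  pooled
}

#' @export
print.crt_pooled <- function(x, ...) {
  cat(sprintf("<Rubin-pooled estimates: M = %d imputations, %g%% normal CIs>\n",
              x$m[1], 100 * (attr(x, "level") %||% 0.95)))
  NextMethod()
}

#' @rdname rubin_pool
#' @param x A `crt_pooled` object.
#' @param ... Unused.
#' @export
glance.crt_pooled <- function(x, ...) {
  tibble::tibble(
    m = x$m[1],
    level = attr(x, "level") %||% 0.95,
    riv1 = (1 + 1 / x$m[1]) * x$between[1] / x$within[1],
    riv2 = (1 + 1 / x$m[1]) * x$between[2] / x$within[2]
  )
}

#' Fit and pool a stack of imputed datasets
#'
#' Convenience wrapper: fits the substantive model ([fit_bivariate_mixed()])
#' to every completed copy of an imputation stack and pools by
#' [rubin_pool()].
#'
#' @param stack A `crt_imputed` stack.
#' @param reml Passed to [fit_bivariate_mixed()].
#' @param level Confidence level.
#' @return A `crt_pooled` tibble.
#' @export
analyse_imputed <- function(stack, reml = TRUE, level = 0.95) {
  stopifnot(inherits(stack, "crt_imputed"))
  fits <- lapply(imputed_sets(stack), fit_bivariate_mixed, reml = reml)
  rubin_pool(fits, level = level)
}

#' Incremental net monetary benefit
#'
#' `INB(lambda) = lambda * delta_Q - delta_C` at willingness-to-pay `lambda`,
#' with variance
#' `lambda^2 var(delta_Q) + var(delta_C) - 2 lambda cov(delta_C, delta_Q)`
#' and a normal confidence interval. In the simulation context `y1` plays the
#' cost and `y2` the health outcome (QALY); pass the estimates accordingly.
#'
#' @param delta_q Incremental health effect (treatment effect on the QALY
#'   outcome).
#' @param delta_c Incremental cost (treatment effect on the cost outcome).
#' @param vcov 2 x 2 covariance matrix of `(delta_c, delta_q)` in that order.
#' @param lambda Willingness-to-pay value(s), currency per outcome unit.
#' @param level Confidence level.
#' @return A `crt_inb` tibble with one row per `lambda`: `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @examples
#' inb(delta_q = -0.05, delta_c = 100,
#'     vcov = matrix(c(1e4, 0, 0, 0.0025), 2), lambda = 20000)
#' @export
inb <- function(delta_q, delta_c, vcov, lambda = 20000, level = 0.95) {
  vcov <- as.matrix(vcov)
  if (any(lambda < 0)) abort("`lambda` must be >= 0")
  if (!isTRUE(all.equal(vcov, t(vcov), tolerance = 1e-8))) {
    abort("`vcov` must be symmetric")
  }
  v <- lambda^2 * vcov[2, 2] + vcov[1, 1] - 2 * lambda * vcov[1, 2]
  if (any(v < 0)) abort("`vcov` implies a negative INB variance")
  est <- lambda * delta_q - delta_c
  z <- z_crit(level)
  out <- tibble::tibble(
    lambda = lambda,
    estimate = est,
    std.error = sqrt(v),
    conf.low = est - z * sqrt(v),
    conf.high = est + z * sqrt(v)
  )
  class(out) <- c("crt_inb", class(out))
  attr(out, "level") <- level
  out
}
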