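# Reduce a complete dataset to the sufficient statistics of the bivariate
# random-intercept model and fit by profiled Nelder-Mead (compiled).
fit_bvmm_core <- function(y, cl, arm_cl, reml = TRUE) {
  nj <- tabulate(cl)
  J <- length(nj)
  ntot <- nrow(y)
  ybar <- rowsum(y, cl) / nj
  W <- crossprod(y - ybar[cl, , drop = FALSE])

  # moment-based starting values: within mean square and between-cluster
  # variance of the cluster means (floored so log-SDs stay finite)
  s2 <- pmax(diag(W) / max(ntot - J, 1), 1e-8)
  rho0 <- W[1, 2] / max(ntot - J, 1) / sqrt(s2[1] * s2[2])
  arm_mean <- rowsum(ybar, arm_cl) / tabulate(arm_cl + 1L)
  dev <- ybar - arm_mean[arm_cl + 1L, , drop = FALSE]
  vb <- pmax(colSums(dev^2) / max(J - 2, 1) - s2 * mean(1 / nj), 0.04 * s2)
  phi0 <- sum(dev[, 1] * dev[, 2]) / max(J - 2, 1) / sqrt(vb[1] * vb[2])
  clamp_r <- function(r) max(min(ifelse(is.finite(r), r, 0), 0.9), -0.9)
  theta0 <- c(0.5 * log(s2), atanh(clamp_r(rho0)),
              0.5 * log(vb), atanh(clamp_r(phi0)))

  fit <- bvmm_fit_cpp(ybar, nj, as.integer(arm_cl), W, ntot, reml,
                      theta0, 2000L, 1e-10, 3L)
  fit$n_used <- ntot
  fit$n_clusters <- J
  fit
}

# Evaluate the model's (restricted) log-likelihood at fixed variance
# components, with the means profiled out; the exact collapsed form is
# checked in tests against direct multivariate-normal density evaluation.
bvmm_loglik <- function(data, sigma1, sigma2, rho, tau1, tau2, phi,
                        reml = FALSE) {
  data <- validate_trial(data)
  cl <- match(data$cluster_id, unique(data$cluster_id))
  arm_cl <- vapply(split(data$arm, cl), `[`, integer(1), 1)
  y <- cbind(data$y1, data$y2)
  nj <- tabulate(cl)
  ybar <- rowsum(y, cl) / nj
  W <- crossprod(y - ybar[cl, , drop = FALSE])
  bvmm_loglik_cpp(sigma1, sigma2, rho, tau1, tau2, phi,
                  ybar, nj, as.integer(arm_cl), W, nrow(y), reml)
}

#' Fit the bivariate random-intercept substantive model
#'
#' Fits, to both arms simultaneously, the bivariate linear mixed model in
#' which each outcome has an intercept and a treatment effect, individuals
#' share correlated cluster random intercepts `(u1, u2) ~ N(0, Phi)` and
#' correlated residuals `(e1, e2) ~ N(0, Sigma)`, with common covariance
#' across arms. Variance components are parameterised as log-SDs and
#' arctanh-correlations; the four fixed effects are profiled out by
#' generalised least squares at each variance value, and the restricted
#' (REML) criterion is maximised by default. The treatment-effect covariance
#' comes from the GLS information.
#'
#' @param data A trial data frame with both outcomes fully observed
#'   (a completed imputation or [complete_cases()] output).
#' @param reml Use the restricted likelihood (default) or plain maximum
#'   likelihood.
#' @return A `crt_bvmm` object with elements `beta` (treatment effects on
#'   `y1`, `y2`), `intercept`, `vcov_treat`, the variance components
#'   (`sigma1`, `sigma2`, `rho`, `tau1`, `tau2`, `phi`), `logLik`,
#'   `converged`, `n_used` and `n_clusters`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' d <- generate_trial(scenario(J = 10, sizes = fixed_sizes(10)), seed = 1)
#' fit <- fit_bivariate_mixed(d)
#' tidy(fit)
#' @export
fit_bivariate_mixed <- function(data, reml = TRUE) {
  data <- validate_trial(data)
  if (any(data$r1 == 1L | data$r2 == 1L)) {
    abort(paste("outcomes must be fully observed; impute first or pass",
                "complete_cases(data)"))
  }
  cl <- match(data$cluster_id, unique(data$cluster_id))
  arm_cl <- vapply(split(data$arm, cl), `[`, integer(1), 1)
  if (any(tabulate(arm_cl + 1L) < 2)) {
    abort("each arm needs at least 2 clusters to fit the mixed model")
  }
  fit <- fit_bvmm_core(cbind(data$y1, data$y2), cl, arm_cl, reml)
  structure(list(
    beta = setNames(as.numeric(fit$beta), c("beta1", "beta2")),
    intercept = setNames(as.numeric(fit$intercept),
                         c("intercept1", "intercept2")),
    vcov_treat = fit$vcov_treat,
    sigma1 = fit$sigma1, sigma2 = fit$sigma2, rho = fit$rho,
    tau1 = fit$tau1, tau2 = fit$tau2, phi = fit$phi,
    logLik = fit$loglik, reml = reml,
    converged = isTRUE(fit$converged),
    n_used = fit$n_used, n_clusters = fit$n_clusters
  ), class = "crt_bvmm")
}

#' @export
print.crt_bvmm <- function(x, ...) {
  cat(sprintf("<bivariate mixed model (%s)%s>\n",
              if (x$reml) "REML" else "ML",
              if (x$converged) "" else ", NOT converged"))
  print(tidy(x))
  cat(sprintf("  sigma = (%.3f, %.3f), rho = %.3f; tau = (%.3f, %.3f), phi = %.3f\n",
              x$sigma1, x$sigma2, x$rho, x$tau1, x$tau2, x$phi))
  invisible(x)
}

#' @rdname fit_bivariate_mixed
#' @param x A `crt_bvmm` object.
#' @param conf.level Confidence level for the normal intervals.
#' @param ... Unused.
#' @export
tidy.crt_bvmm <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_treat))
  z <- z_crit(conf.level)
  tibble::tibble(
    term = c("beta1", "beta2"),
    estimate = unname(x$beta),
    std.error = se,
    statistic = unname(x$beta) / se,
    conf.low = unname(x$beta) - z * se,
    conf.high = unname(x$beta) + z * se
  )
}

#' @rdname fit_bivariate_mixed
#' @export
glance.crt_bvmm <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, converged = x$converged,
    nobs = x$n_used, n.clusters = x$n_clusters,
    sigma1 = x$sigma1, sigma2 = x$sigma2, rho = x$rho,
    tau1 = x$tau1, tau2 = x$tau2, phi = x$phi,
    REML = x$reml
  )
}
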