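#' Control parameters for the multilevel Gibbs sampler
#'
#' @param burn_in Iterations discarded before the first imputation is taken
#'   (default 1000). With few clusters per arm (5 or fewer) and appreciable
#'   clustering, the cluster-variance chain mixes slowly and a burn-in of
#'   5000 is recommended.
#' @param thin Iterations between successive imputations (default 1000).
#' @param prior_df Degrees of freedom of the diffuse inverse-Wishart priors on
#'   the residual and cluster-effect covariance matrices (default 2, the
#'   dimension -- the most diffuse proper choice).
#' @param prior_scale Scale matrix of those priors (default identity).
#' @return A `crt_gibbs_control` list.
#' @export
gibbs_control <- function(burn_in = 1000, thin = 1000, prior_df = 2,
                          prior_scale = diag(2)) {
  if (burn_in < 0) abort("`burn_in` must be >= 0")
  if (thin < 1) abort("`thin` must be >= 1")
  if (prior_df < 2) abort("`prior_df` must be >= 2 (the dimension)")
  prior_scale <- as.matrix(prior_scale)
  if (!isTRUE(all.equal(prior_scale, t(prior_scale))) ||
      any(eigen(prior_scale, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`prior_scale` must be symmetric positive definite")
  }
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_df = prior_df, prior_scale = prior_scale),
            class = "crt_gibbs_control")
}

# Run the Gibbs sampler on one arm's matrices. Exposed internally so tests
# can examine parameter chains; users go through impute_mmi().
mmi_chain <- function(y, X, cluster, M, control = gibbs_control()) {
  storage.mode(y) <- "double"
  r <- matrix(as.integer(is.na(y)), ncol = 2)
  if ((M - 1) * as.double(control$thin) + control$burn_in > 5e8) {
    abort("burn_in + M * thin is implausibly large; refusing to run")
  }
  gibbs_bivariate_impute(y, X, as.integer(cluster) - 1L, r,
                         as.integer(M), control$burn_in, control$thin,
                         control$prior_df, control$prior_scale)
}

#' Multilevel joint-model multiple imputation (MMI)
#'
#' Imputes the bivariate outcomes from a bivariate random-intercept
#' regression fitted separately within each treatment arm: per-cluster random
#' effects `(u1, u2)` with covariance `Phi`, residuals with covariance
#' `Sigma`, noninformative priors on the coefficients and diffuse
#' inverse-Wishart priors on both covariance matrices. A Gibbs sampler cycles
#' through the full conditionals (cluster effects, `Phi`, `Sigma`,
#' coefficients, missing outcomes); the first completed dataset is taken
#' after `control$burn_in` iterations and subsequent ones every
#' `control$thin` iterations.
#'
#' @inheritParams impute_smi
#' @param control A [gibbs_control()].
#' @return A `crt_imputed` stack of `M` completed copies.
#' @export
impute_mmi <- function(data, M = 10, aux = c("x", "w"),
                       control = gibbs_control(), seed = NULL) {
  data <- validate_trial(data)
  stopifnot(inherits(control, "crt_gibbs_control"))
  if (M < 1) abort("`M` must be >= 1")
  seed <- seed %||% sample.int(2147483646, 1)
  copies <- rep(list(data), M)
  for (k in 0:1) {
    idx <- which(data$arm == k)
    sub <- data[idx, , drop = FALSE]
    cl <- match(sub$cluster_id, unique(sub$cluster_id))
    if (max(cl) < 2) abort(sprintf("arm %d has fewer than 2 clusters", k))
    y <- cbind(sub$y1, sub$y2)
    X <- make_design(sub, aux)
    set.seed(derive_seed(seed, k))
    res <- mmi_chain(y, X, cl, M, control)
    for (m in seq_len(M)) {
      copies[[m]]$y1[idx] <- res$imputations[[m]][, 1]
      copies[[m]]$y2[idx] <- res$imputations[[m]][, 2]
    }
  }
  new_imputed_stack(copies, data, "mmi")
}
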