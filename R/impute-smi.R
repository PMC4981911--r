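# Build the design matrix (intercept + auxiliary covariates) for one arm.
make_design <- function(sub, aux) {
  n <- nrow(sub)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (a in aux) {
    if (!a %in% names(sub)) abort(sprintf("auxiliary column `%s` not found", a))
    X <- cbind(X, sub[[a]])
    colnames(X)[ncol(X)] <- a
  }
  X
}

# Shared engine loop: `design_fun(sub)` returns the per-arm design matrix for
# all rows of that arm; imputation m of arm k uses the child stream
# derive_seed(seed, k, m), so arms are imputed independently and M can be
# extended without replaying earlier imputations.
impute_joint_normal <- function(data, M, design_fun, method, seed) {
  data <- validate_trial(data)
  if (M < 1) abort("`M` must be >= 1")
  seed <- seed %||% sample.int(2147483646, 1)
  copies <- rep(list(data), M)
  for (k in 0:1) {
    idx <- which(data$arm == k)
    sub <- data[idx, , drop = FALSE]
    X <- design_fun(sub)
    cc <- sub$r1 == 0L & sub$r2 == 0L
    if (sum(cc) <= ncol(X) + 2) {
      abort(sprintf(
        "arm %d has %d complete rows for a %d-column design; too few for a proper posterior",
        k, sum(cc), ncol(X)))
    }
    y_cc <- cbind(sub$y1, sub$y2)[cc, , drop = FALSE]
    X_cc <- X[cc, , drop = FALSE]
    y0 <- cbind(sub$y1, sub$y2)
    r <- cbind(sub$r1, sub$r2)
    for (m in seq_len(M)) {
      set.seed(derive_seed(seed, k, m))
      post <- draw_regression_posterior(y_cc, X_cc)
      mu <- X %*% post$coef
      yfill <- fill_bivariate(y0, r, mu, post$resid_cov)
      copies[[m]]$y1[idx] <- yfill[, 1]
      copies[[m]]$y2[idx] <- yfill[, 2]
    }
  }
  new_imputed_stack(copies, data, method)
}

#' Single-level multiple imputation (SMI)
#'
#' Imputes the bivariate outcomes from a joint-normal regression on the
#' auxiliary covariates, fitted separately within each treatment arm and
#' ignoring any within-cluster dependency beyond what the cluster-level
#' covariate explains. Each imputation takes a fresh draw from the conjugate
#' posterior ([draw_regression_posterior()]) before sampling the missing
#' values, so the imputations are proper. Records with one outcome observed
#' are completed from the conditional normal given the observed co-outcome.
#'
#' Because both outcomes are Gaussian, cycling univariate chained equations
#' and sampling the joint normal coincide; the joint conjugate form is used
#' directly and the `cycles` argument is accepted only for interface
#' compatibility with chained-equation implementations (it has no effect).
#'
#' @param data A trial data frame with missing outcomes.
#' @param M Number of imputations.
#' @param aux Auxiliary covariate columns for the imputation model (default
#'   the individual- and cluster-level covariates `x` and `w`).
#' @param seed Optional seed; imputation `m` of arm `k` uses its own derived
#'   child stream.
#' @param cycles Ignored; see Details.
#' @return A `crt_imputed` stack of `M` completed copies.
#' @examples
#' sc <- scenario(J = 6, sizes = fixed_sizes(20),
#'                mechanism = mar_mechanism("individual", eta = 1))
#' d <- apply_missingness(generate_trial(sc, seed = 1),
#'                        sc$mechanism, seed = 2)
#' impute_smi(d, M = 3, seed = 3)
#' @export
impute_smi <- function(data, M = 10, aux = c("x", "w"), seed = NULL,
                       cycles = 10) {
  impute_joint_normal(data, M, function(sub) make_design(sub, aux),
                      "smi", seed)
}
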