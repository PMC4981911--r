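# Builders and independent oracles shared across the test files. Everything
# here is deliberately written from first principles (direct covariance
# assembly, closed-form posteriors, quadrature) so it checks the package's
# collapsed/conjugate computations through an independent route.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small fully observed two-arm trial table built by hand.
toy_trial <- function(y1 = NULL, y2 = NULL, sizes = c(2, 2, 2, 2),
                      arms = c(0, 0, 1, 1), x = NULL, w = NULL) {
  n <- sum(sizes)
  cl <- rep(seq_along(sizes), sizes)
  if (is.null(y1)) y1 <- seq_len(n)
  if (is.null(y2)) y2 <- rev(seq_len(n))
  tibble::tibble(
    individual_id = as.character(seq_len(n)),
    cluster_id = paste0("cl", cl),
    arm = arms[cl],
    x = x %||% rep(0, n),
    w = (w %||% rep(0, length(sizes)))[cl],
    y1 = as.numeric(y1),
    y2 = as.numeric(y2)
  )
}

# Direct 2n-dimensional multivariate-normal evaluation of the bivariate
# random-intercept model's profiled (restricted) log-likelihood: assemble the
# full covariance, profile the four cluster-constant fixed effects by GLS,
# and call mvtnorm::dmvnorm. Used as the oracle for bvmm_loglik.
brute_force_loglik <- function(data, sigma1, sigma2, rho, tau1, tau2, phi,
                               reml = FALSE) {
  n <- nrow(data)
  cl <- match(data$cluster_id, unique(data$cluster_id))
  Sig <- matrix(c(sigma1^2, rho * sigma1 * sigma2,
                  rho * sigma1 * sigma2, sigma2^2), 2)
  Phi <- matrix(c(tau1^2, phi * tau1 * tau2,
                  phi * tau1 * tau2, tau2^2), 2)
  # observation order: (y1_1..y1_n, y2_1..y2_n)
  V <- matrix(0, 2 * n, 2 * n)
  for (l1 in 1:2) for (l2 in 1:2) {
    blk <- outer(cl, cl, "==") * Phi[l1, l2] + diag(n) * Sig[l1, l2]
    V[(l1 - 1) * n + 1:n, (l2 - 1) * n + 1:n] <- blk
  }
  X <- cbind(int1 = rep(c(1, 0), each = n), int2 = rep(c(0, 1), each = n),
             trt1 = c(data$arm, rep(0, n)), trt2 = c(rep(0, n), data$arm))
  y <- c(data$y1, data$y2)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  ll <- mvtnorm::dmvnorm(y, as.numeric(X %*% beta), V, log = TRUE)
  if (reml) ll <- ll - 0.5 * determinant(XtVX, logarithm = TRUE)$modulus[1]
  ll
}

# --- quadrature oracle for the multilevel Gibbs sampler -------------------
# One-arm instance: covariance structure of the stacked observation vector,
# flat prior on the two outcome intercepts integrated analytically, diffuse
# IW(prior_df, prior_scale) priors on Sigma and Phi integrated by tensor
# Gauss-Legendre quadrature in (log s1, log s2, atanh rho, log t1, log t2,
# atanh phi). Returns the posterior predictive mean of the missing entries.

gibbs_oracle_logpost <- function(th, y, cl, miss, prior_df, prior_scale) {
  s1 <- exp(th[1]); s2 <- exp(th[2]); rho <- tanh(th[3])
  t1 <- exp(th[4]); t2 <- exp(th[5]); phi <- tanh(th[6])
  n <- length(cl)
  Sig <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2)
  Phi <- matrix(c(t1^2, phi * t1 * t2, phi * t1 * t2, t2^2), 2)
  V <- matrix(0, 2 * n, 2 * n)
  for (l1 in 1:2) for (l2 in 1:2) {
    V[(l1 - 1) * n + 1:n, (l2 - 1) * n + 1:n] <-
      outer(cl, cl, "==") * Phi[l1, l2] + diag(n) * Sig[l1, l2]
  }
  X <- cbind(rep(c(1, 0), each = n), rep(c(0, 1), each = n))
  obs <- setdiff(seq_len(2 * n), miss)
  Vo <- V[obs, obs]
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  R <- chol(Vo)
  Vio <- chol2inv(R)
  XtVX <- t(Xo) %*% Vio %*% Xo
  bhat <- solve(XtVX, t(Xo) %*% Vio %*% yo)
  resid <- yo - Xo %*% bhat
  # flat-prior marginal over the mean parameters (restricted likelihood)
  ll <- -sum(log(diag(R))) - 0.5 * determinant(XtVX, TRUE)$modulus[1] -
    0.5 * sum(resid * (Vio %*% resid))
  # IW priors and the Jacobian of (Sigma, Phi) -> transformed coordinates
  lp_iw <- function(M, d2) {
    -(prior_df + 3) / 2 * determinant(M, TRUE)$modulus[1] -
      0.5 * sum(diag(prior_scale %*% solve(M)))
  }
  ljac <- log(4) + 3 * log(s1) + 3 * log(s2) + log(1 - rho^2) +
    log(4) + 3 * log(t1) + 3 * log(t2) + log(1 - phi^2)
  # predictive mean of the missing entries at these parameter values
  pm <- X[miss, , drop = FALSE] %*% bhat +
    V[miss, obs, drop = FALSE] %*% (Vio %*% resid)
  list(lp = as.numeric(ll + lp_iw(Sig) + lp_iw(Phi) + ljac),
       pred_mean = as.numeric(pm))
}

# Tensor-product Gauss-Legendre quadrature of the posterior predictive mean.
gibbs_oracle_mean <- function(y, cl, miss, prior_df = 2,
                              prior_scale = diag(2),
                              centre, halfwidth, n_nodes = 8) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  nodes <- lapply(seq_along(centre),
                  function(k) centre[k] + halfwidth[k] * gl$x)
  wts <- lapply(seq_along(centre), function(k) gl$w * halfwidth[k])
  grid <- as.matrix(expand.grid(nodes))
  wgrid <- as.matrix(expand.grid(wts))
  logw <- numeric(nrow(grid))
  pmean <- matrix(0, nrow(grid), length(miss))
  for (g in seq_len(nrow(grid))) {
    ev <- gibbs_oracle_logpost(grid[g, ], y, cl, miss, prior_df, prior_scale)
    logw[g] <- ev$lp + sum(log(wgrid[g, ]))
    pmean[g, ] <- ev$pred_mean
  }
  w <- exp(logw - max(logw))
  colSums(pmean * w) / sum(w)
}
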