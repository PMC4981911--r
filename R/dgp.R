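#' Cluster-size specifications
#'
#' `fixed_sizes(n)` gives every cluster the same size; `gamma_sizes()` draws
#' sizes by rounding a Gamma random variable with the given mean and
#' coefficient of variation (shape `1/cv^2`, scale `mean * cv^2`), flooring at
#' `min_size` so that within-cluster variances stay estimable.
#'
#' @param n Common cluster size.
#' @param mean Mean cluster size of the Gamma draw.
#' @param cv Coefficient of variation `SD(n)/E(n)` of the Gamma draw.
#' @param min_size Minimum size after rounding (default 2).
#' @return A size specification used by [scenario()] and
#'   [draw_cluster_sizes()].
#' @examples
#' draw_cluster_sizes(5, gamma_sizes(20, 0.5), seed = 1)
#' @export
fixed_sizes <- function(n) {
  if (!is.finite(n) || n < 1) abort("fixed cluster size must be >= 1")
  structure(list(kind = "fixed", n = as.integer(n)), class = "crt_sizes")
}

#' @rdname fixed_sizes
#' @export
gamma_sizes <- function(mean, cv, min_size = 2) {
  if (!is.finite(mean) || mean < 1) abort("gamma mean size must be >= 1")
  if (!is.finite(cv) || cv <= 0) abort("gamma coefficient of variation must be > 0")
  if (min_size < 1) abort("`min_size` must be >= 1")
  structure(list(kind = "gamma", mean = mean, cv = cv,
                 min_size = as.integer(min_size)),
            class = "crt_sizes")
}

#' @export
print.crt_sizes <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("<cluster sizes: fixed n_j = %d>\n", x$n))
  } else {
    cat(sprintf("<cluster sizes: rounded Gamma(mean %g, cv %g), min %d>\n",
                x$mean, x$cv, x$min_size))
  }
  invisible(x)
}

#' Cluster random-effect SD from an intra-cluster correlation
#'
#' Inverts the conditional ICC definition `icc = tau^2 / (tau^2 + sigma^2)`
#' (the share of residual-scale outcome variance between clusters, excluding
#' variance explained by covariates), giving
#' `tau = sigma * sqrt(icc / (1 - icc))`.
#'
#' @param icc Intra-cluster correlation in `[0, 1)`.
#' @param sigma Individual-level residual SD (> 0).
#' @return The cluster random-intercept SD `tau`.
#' @examples
#' tau_from_icc(0.2, 40) # 20
#' @export
tau_from_icc <- function(icc, sigma) {
  check_prob(icc, "icc", open = FALSE)
  if (!all(is.finite(sigma)) || any(sigma <= 0)) abort("`sigma` must be > 0")
  sigma * sqrt(icc / (1 - icc))
}

#' Draw the cluster sizes of one trial arm
#'
#' @param J Number of clusters.
#' @param sizes A specification from [fixed_sizes()] or [gamma_sizes()].
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return An integer vector of `J` cluster sizes.
#' @export
draw_cluster_sizes <- function(J, sizes, seed = NULL) {
  if (!is.finite(J) || J < 1) abort("`J` must be >= 1")
  if (!inherits(sizes, "crt_sizes")) abort("`sizes` must come from fixed_sizes() or gamma_sizes()")
  with_seed(seed, {
    if (sizes$kind == "fixed") {
      rep(sizes$n, J)
    } else {
      shape <- 1 / sizes$cv^2
      scale <- sizes$mean * sizes$cv^2
      pmax(sizes$min_size, as.integer(round(rgamma(J, shape = shape, scale = scale))))
    }
  })
}

#' Define a simulation scenario
#'
#' One cell of the factorial design: a two-arm cluster randomised trial with
#' `J` clusters per arm, bivariate normal outcomes generated as
#' \deqn{Y_1 = 100 + 120k + \beta_{w,1} W_j + \beta_{x,1} X_i + u_{1,j} + e_{1,i}}
#' \deqn{Y_2 = 50 + 10k + \beta_{w,2} W_j + \beta_{x,2} X_i + u_{2,j} + e_{2,i}}
#' with individual residuals `(e1, e2)` bivariate normal (SDs `sigma1`,
#' `sigma2`, correlation `rho`) and cluster random intercepts `(u1, u2)`
#' bivariate normal with SDs implied by the ICCs (via [tau_from_icc()]) and
#' correlation `phi`. `X` is an individual-level and `W` a cluster-level
#' standard-normal auxiliary covariate; neither enters the substantive model.
#'
#' @param J Clusters per arm.
#' @param sizes Cluster-size specification ([fixed_sizes()]/[gamma_sizes()]).
#' @param icc1,icc2 Intra-cluster correlations of the two outcomes.
#' @param mechanism Optional non-response mechanism ([mar_mechanism()]).
#' @param intercept1,intercept2,effect1,effect2 Fixed-effect constants.
#' @param sigma1,sigma2,rho Residual SDs and correlation.
#' @param phi Correlation of the two cluster random intercepts.
#' @param beta_x1,beta_x2,beta_w1,beta_w2 Auxiliary-covariate effects.
#'   Defaults: the individual-level covariate is strongly prognostic (half
#'   the residual SD of each outcome) and the cluster-level covariate mildly
#'   so (5% of the residual SD); because the substantive model excludes the
#'   covariates, `beta_w` acts as extra cluster-level variance in the
#'   analysis, and these defaults keep the implied interval widths
#'   realistic for trials of this size.
#' @param M Number of imputations downstream engines should use.
#' @param seed Optional per-scenario master seed.
#' @return A `crt_scenario` object.
#' @examples
#' sc <- scenario(J = 25, sizes = fixed_sizes(10), icc1 = 0.2, icc2 = 0.05)
#' generate_trial(sc, seed = 1)
#' @export
scenario <- function(J = 25, sizes = fixed_sizes(10),
                     icc1 = 0.01, icc2 = 0.01,
                     mechanism = NULL,
                     intercept1 = 100, intercept2 = 50,
                     effect1 = 120, effect2 = 10,
                     sigma1 = 40, sigma2 = 20, rho = 0.1, phi = 0.1,
                     beta_x1 = 20, beta_x2 = 10,
                     beta_w1 = 2, beta_w2 = 1,
                     M = 10, seed = NULL) {
  if (!is.finite(J) || J < 1) abort("`J` must be >= 1")
  check_prob(c(icc1, icc2), "icc", open = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0) abort("residual SDs must be > 0")
  if (abs(rho) >= 1 || abs(phi) >= 1) abort("correlations must lie in (-1, 1)")
  if (!inherits(sizes, "crt_sizes")) abort("`sizes` must come from fixed_sizes() or gamma_sizes()")
  structure(list(
    J = as.integer(J), sizes = sizes, icc1 = icc1, icc2 = icc2,
    mechanism = mechanism,
    intercept1 = intercept1, intercept2 = intercept2,
    effect1 = effect1, effect2 = effect2,
    sigma1 = sigma1, sigma2 = sigma2, rho = rho, phi = phi,
    beta_x1 = beta_x1, beta_x2 = beta_x2,
    beta_w1 = beta_w1, beta_w2 = beta_w2,
    tau1 = tau_from_icc(icc1, sigma1), tau2 = tau_from_icc(icc2, sigma2),
    M = as.integer(M), seed = seed
  ), class = "crt_scenario")
}

#' @export
print.crt_scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario: J = %d/arm, ICC = (%.2f, %.2f), tau = (%.2f, %.2f), M = %d>\n",
    x$J, x$icc1, x$icc2, x$tau1, x$tau2, x$M))
  print(x$sizes)
  if (!is.null(x$mechanism)) print(x$mechanism)
  invisible(x)
}

#' Generate one complete trial dataset
#'
#' Allocates `J` clusters to each arm, draws cluster sizes, standard-normal
#' covariates (`x` per individual, `w` per cluster), correlated cluster
#' random intercepts and individual residuals, and builds the two outcomes
#' from the scenario's fixed effects. No missingness is imposed; see
#' [apply_missingness()].
#'
#' @param scenario A [scenario()].
#' @param seed Optional seed; identical `(scenario, seed)` give identical data.
#' @return A complete trial tibble (all `r1 = r2 = 0`).
#' @export
generate_trial <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "crt_scenario")) abort("`scenario` must be a crt_scenario")
  with_seed(seed %||% scenario$seed, {
    sc <- scenario
    nj <- c(draw_cluster_sizes(sc$J, sc$sizes), draw_cluster_sizes(sc$J, sc$sizes))
    n_cl <- 2L * sc$J
    arm_cl <- rep(c(0L, 1L), each = sc$J)
    n <- sum(nj)
    cl_of <- rep.int(seq_len(n_cl), nj)

    w_cl <- rnorm(n_cl)
    u <- rbvnorm(n_cl, sc$tau1, sc$tau2, sc$phi)
    x <- rnorm(n)
    e <- rbvnorm(n, sc$sigma1, sc$sigma2, sc$rho)

    arm <- arm_cl[cl_of]
    y1 <- sc$intercept1 + sc$effect1 * arm + sc$beta_w1 * w_cl[cl_of] +
      sc$beta_x1 * x + u[cl_of, 1] + e[, 1]
    y2 <- sc$intercept2 + sc$effect2 * arm + sc$beta_w2 * w_cl[cl_of] +
      sc$beta_x2 * x + u[cl_of, 2] + e[, 2]

    cluster_id <- sprintf("a%d_c%02d", arm_cl, c(seq_len(sc$J), seq_len(sc$J)))
    tibble::tibble(
      individual_id = sprintf("%s_i%03d", cluster_id[cl_of],
                              sequence(nj)),
      cluster_id = cluster_id[cl_of],
      arm = arm,
      x = x,
      w = w_cl[cl_of],
      y1 = y1,
      y2 = y2,
      r1 = 0L,
      r2 = 0L
    )
  })
}
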