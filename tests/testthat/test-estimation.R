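test_that("profiled likelihood matches direct multivariate-normal evaluation", {
  # tiny unbalanced instance: 3 clusters (sizes 3, 2, 3) across two arms
  set.seed(121)
  d <- toy_trial(sizes = c(3, 2, 3), arms = c(0, 1, 1),
                 y1 = rnorm(8, 10, 2), y2 = rnorm(8, -4, 1))
  cases <- list(c(2, 1, 0.3, 1.5, 0.8, -0.2),
                c(1, 1, 0, 0.5, 0.5, 0),
                c(3, 0.7, -0.5, 2, 0.1, 0.6))
  for (p in cases) {
    for (reml in c(FALSE, TRUE)) {
      ours <- crtmi:::bvmm_loglik(d, p[1], p[2], p[3], p[4], p[5], p[6],
                                  reml = reml)
      brute <- brute_force_loglik(d, p[1], p[2], p[3], p[4], p[5], p[6],
                                  reml = reml)
      expect_equal(ours, brute, tolerance = 1e-6)
    }
  }
  # and at the fitted optimum (two clusters per arm so the model is fittable)
  d4 <- toy_trial(sizes = c(2, 2, 2, 3), arms = c(0, 0, 1, 1),
                  y1 = rnorm(9, 10, 2), y2 = rnorm(9, -4, 1))
  f <- fit_bivariate_mixed(d4, reml = FALSE)
  expect_equal(f$logLik,
               brute_force_loglik(d4, f$sigma1, f$sigma2, f$rho,
                                  f$tau1, f$tau2, f$phi),
               tolerance = 1e-6)
})

test_that("balanced designs give the arm-mean difference as GLS estimate", {
  d <- toy_trial(sizes = c(2, 2, 2, 2), arms = c(0, 0, 1, 1),
                 y1 = c(1, 1, 3, 3, 2, 2, 6, 6),
                 y2 = c(4, 4, 8, 8, 5, 5, 7, 7))
  f <- fit_bivariate_mixed(d)
  expect_equal(unname(f$beta["beta1"]), 2, tolerance = 1e-6)
  expect_equal(unname(f$beta["beta2"]), 0, tolerance = 1e-6)
  expect_equal(unname(f$intercept["intercept1"]), 2, tolerance = 1e-6)
})

test_that("variance components recover truth and respect the boundary", {
  sc <- scenario(J = 40, sizes = fixed_sizes(25), icc1 = 0.2, icc2 = 0.05,
                 beta_x1 = 0, beta_x2 = 0, beta_w1 = 0, beta_w2 = 0)
  d <- generate_trial(sc, seed = 131)
  f <- fit_bivariate_mixed(d)
  expect_true(f$converged)
  expect_equal(f$sigma1, 40, tolerance = 0.05)
  expect_equal(f$sigma2, 20, tolerance = 0.05)
  expect_equal(f$tau1, 20, tolerance = 0.35)
  se <- sqrt(diag(f$vcov_treat))
  expect_true(abs(f$beta["beta1"] - 120) < 3 * se[1])
  expect_true(abs(f$beta["beta2"] - 10) < 3 * se[2])

  # tau -> 0 data: estimate collapses towards the boundary (well below the
  # residual SD of 40), beta still right
  sc0 <- scenario(J = 40, sizes = fixed_sizes(60), icc1 = 0, icc2 = 0,
                  beta_x1 = 0, beta_x2 = 0, beta_w1 = 0, beta_w2 = 0)
  d0 <- generate_trial(sc0, seed = 132)
  f0 <- fit_bivariate_mixed(d0)
  expect_lt(f0$tau1, 4)
  expect_true(abs(f0$beta["beta1"] - 120) <
                3 * sqrt(f0$vcov_treat[1, 1]))
})

test_that("the bivariate fit agrees with an independent univariate mixed model", {
  # rho = phi = 0: the bivariate model decouples; lme4 is the oracle per
  # outcome (REML in both)
  sc <- scenario(J = 20, sizes = fixed_sizes(15), icc1 = 0.2, icc2 = 0.1,
                 rho = 0, phi = 0)
  d <- generate_trial(sc, seed = 141)
  f <- fit_bivariate_mixed(d)
  lmer_fit <- lme4::lmer(y1 ~ arm + (1 | cluster_id), data = d, REML = TRUE)
  b_lmer <- lme4::fixef(lmer_fit)[["arm"]]
  se_lmer <- sqrt(vcov(lmer_fit)["arm", "arm"])
  expect_equal(unname(f$beta["beta1"]), b_lmer, tolerance = 0.01)
  expect_equal(sqrt(f$vcov_treat[1, 1]), se_lmer, tolerance = 0.03)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  expect_equal(f$tau1, vc$sdcor[1], tolerance = 0.05)
  expect_equal(f$sigma1, vc$sdcor[2], tolerance = 0.02)
})

test_that("single-cluster arms are rejected", {
  d <- toy_trial(sizes = c(3, 3, 3), arms = c(0, 0, 1))
  expect_error(fit_bivariate_mixed(d), "at least 2 clusters")
  dm <- toy_trial()
  dm$y1[1] <- NA
  dm$r1 <- as.integer(is.na(dm$y1))
  expect_error(fit_bivariate_mixed(dm), "fully observed")
})

test_that("Rubin's rules pool point estimates and variances correctly", {
  mk <- function(est, v) {
    structure(list(beta = c(beta1 = est, beta2 = 0),
                   vcov_treat = diag(c(v, 1)), converged = TRUE),
              class = "crt_bvmm")
  }
  # hand-computed example: estimates {1, 3}, variances {1, 1}
  p <- rubin_pool(list(mk(1, 1), mk(3, 1)))
  expect_equal(p$estimate[1], 2)
  expect_equal(p$within[1], 1)
  expect_equal(p$between[1], 2)
  expect_equal(p$total[1], 4) # 1 + (1 + 1/2) * 2
  expect_equal(p$std.error[1], 2)

  # identical fits: between-variance 0, total = within
  p2 <- rubin_pool(list(mk(5, 2), mk(5, 2), mk(5, 2)))
  expect_equal(p2$between[1], 0)
  expect_equal(p2$total[1], p2$within[1])
  expect_equal(p2$estimate[1], 5)

  expect_error(rubin_pool(list(mk(1, 1))), "at least 2")
  expect_warning(
    expect_error(rubin_pool(list(mk(1, 1), {
      f <- mk(2, 1); f$converged <- FALSE; f
    })), "at least 2"),
    "non-converged")
})

test_that("T >= W with equality only for identical estimates", {
  set.seed(151)
  for (i in 1:20) {
    ests <- rnorm(5)
    fits <- lapply(ests, function(e) {
      structure(list(beta = c(e, -e), vcov_treat = diag(runif(2, 0.5, 2)),
                     converged = TRUE), class = "crt_bvmm")
    })
    p <- rubin_pool(fits)
    expect_true(all(p$total >= p$within))
    expect_true(all(p$total > p$within)) # estimates differ almost surely
    expect_true(all(p$between >= 0))
    expect_true(all(p$conf.low <= p$estimate & p$estimate <= p$conf.high))
  }
})

test_that("normal confidence intervals have the right quantiles", {
  base <- tibble::tibble(term = "q", estimate = 0, total = 1)
  ci <- make_ci(base, 0.95)
  expect_equal(ci$conf.low, -1.959964, tolerance = 1e-6)
  expect_equal(ci$conf.high, 1.959964, tolerance = 1e-6)
  ci90 <- make_ci(tibble::tibble(estimate = 10, total = 4), 0.90)
  expect_equal(ci90$conf.low, 10 - 1.644854 * 2, tolerance = 1e-5)
  expect_equal(ci90$conf.high, 13.28971, tolerance = 1e-5)
  degenerate <- make_ci(tibble::tibble(estimate = 3, total = 0), 0.95)
  expect_equal(degenerate$conf.low, 3)
  expect_equal(degenerate$conf.high, 3)
  expect_error(make_ci(base, 1.2), "level")
})

test_that("incremental net benefit follows its closed form", {
  # lambda = 0 collapses to minus the incremental cost
  r0 <- inb(delta_q = -0.05, delta_c = 100,
            vcov = matrix(c(1e4, 0, 0, 0.0025), 2), lambda = 0)
  expect_equal(r0$estimate, -100)
  expect_equal(r0$std.error, 100)
  # direct formula at lambda = 20000
  r <- inb(-0.05, 100, matrix(c(1e4, 0, 0, 0.0025), 2), lambda = 20000)
  expect_equal(r$estimate, -1100)
  expect_equal(r$std.error, sqrt(1.01e6), tolerance = 1e-9)
  # zero effects: zero INB at any willingness to pay
  rz <- inb(0, 0, diag(2), lambda = c(0, 1e4, 5e4))
  expect_equal(rz$estimate, c(0, 0, 0))
  expect_error(inb(1, 1, diag(2), lambda = -5), "lambda")
  expect_error(inb(1, 1, matrix(c(1, 3, 3, 1), 2), lambda = 1),
               "negative INB variance")
})
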