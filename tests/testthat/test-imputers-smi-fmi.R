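# One moderately missing dataset reused across engine contract tests.
masked_fixture <- function(seed = 1, J = 8, nj = 15) {
  sc <- scenario(J = J, sizes = fixed_sizes(nj), icc1 = 0.2, icc2 = 0.05,
                 mechanism = mar_mechanism("both", eta = 1))
  apply_missingness(generate_trial(sc, seed = seed), sc$mechanism,
                    seed = seed + 100)
}

test_that("all engines preserve observed values and are proper", {
  dm <- masked_fixture()
  engines <- list(
    smi = function(d) impute_smi(d, M = 6, seed = 5),
    fmi = function(d) impute_fmi(d, M = 6, seed = 5),
    mmi = function(d) impute_mmi(d, M = 6, control = gibbs_control(100, 20),
                                 seed = 5)
  )
  for (nm in names(engines)) {
    st <- engines[[nm]](dm)
    expect_s3_class(st, "crt_imputed")
    sets <- imputed_sets(st)
    expect_length(sets, 6)
    for (d in sets) {
      expect_false(anyNA(d$y1) || anyNA(d$y2))
      # observed entries equal the source exactly
      expect_identical(d$y1[dm$r1 == 0], dm$y1[dm$r1 == 0])
      expect_identical(d$y2[dm$r2 == 0], dm$y2[dm$r2 == 0])
    }
    # properness: imputed entries vary across imputations
    miss1 <- which(dm$r1 == 1)
    vals <- sapply(sets, function(d) d$y1[miss1])
    expect_true(all(apply(vals, 1, var) > 0))
  }
})

test_that("a dataset with no missing values yields M identical copies", {
  d0 <- generate_trial(scenario(J = 5, sizes = fixed_sizes(12)), seed = 2)
  for (st in list(impute_smi(d0, M = 3, seed = 1),
                  impute_fmi(d0, M = 3, seed = 1),
                  impute_mmi(d0, M = 3, control = gibbs_control(50, 10),
                             seed = 1))) {
    for (d in imputed_sets(st)) {
      expect_equal(d$y1, d0$y1)
      expect_equal(d$y2, d0$y2)
    }
  }
})

test_that("arms are imputed independently", {
  dm <- masked_fixture()
  perturbed <- dm
  in1 <- perturbed$arm == 1
  perturbed$y1[in1] <- perturbed$y1[in1] + 1000
  perturbed$y2[in1] <- perturbed$y2[in1] - 500
  for (fn in list(function(d) impute_smi(d, M = 3, seed = 9),
                  function(d) impute_fmi(d, M = 3, seed = 9),
                  function(d) impute_mmi(d, M = 3,
                                         control = gibbs_control(50, 10),
                                         seed = 9))) {
    a <- fn(dm)
    b <- fn(perturbed)
    expect_identical(a$y1[a$arm == 0], b$y1[b$arm == 0])
    expect_identical(a$y2[a$arm == 0], b$y2[b$arm == 0])
  }
})

test_that("SMI preserves outcome means under MCAR with null covariate effects", {
  sc <- scenario(J = 50, sizes = fixed_sizes(100), icc1 = 0, icc2 = 0,
                 beta_x1 = 0, beta_x2 = 0, beta_w1 = 0, beta_w2 = 0,
                 mechanism = mar_mechanism("individual", eta = 0,
                                           targets = c(0.3, 0.3)))
  dm <- apply_missingness(generate_trial(sc, seed = 31), sc$mechanism,
                          seed = 32)
  st <- impute_smi(dm, M = 5, seed = 33)
  obs_mean <- mean(dm$y1[dm$r1 == 0])
  imp_mean <- mean(st$y1[st$r1 == 1])
  n_imp <- sum(st$r1 == 1)
  expect_true(abs(imp_mean - obs_mean) < 4 * sd(dm$y1, na.rm = TRUE) /
                sqrt(n_imp / 5))
})

test_that("SMI exploits the observed co-outcome through the conditional normal", {
  # near-deterministic outcome correlation: imputed y1 must track y2
  set.seed(41)
  n <- 200
  z <- rnorm(n)
  d <- toy_trial(sizes = rep(n / 4, 4),
                 y1 = 10 + 5 * (0.99 * z + sqrt(1 - 0.99^2) * rnorm(n)),
                 y2 = 3 + 2 * z, x = rnorm(n), w = rnorm(4))
  d$y1[sample(n, 60)] <- NA
  d$r1 <- as.integer(is.na(d$y1))
  d <- validate_trial(d)
  st <- impute_smi(d, M = 2, seed = 42)
  first <- imputed_sets(st)[[1]]
  miss <- d$r1 == 1
  expect_gt(cor(first$y1[miss], d$y2[miss], method = "spearman"), 0.9)
})

test_that("the reference cluster is the nearest to the arm mean, ties to first", {
  # cluster means 10, 20, 30 with unequal sizes: arm mean 21 -> cluster 'cl2'
  d <- toy_trial(sizes = c(3, 3, 4), arms = c(0, 0, 0),
                 y1 = c(10, 10, 10, 20, 20, 20, 30, 30, 30, 30),
                 y2 = rep(1, 10))
  expect_equal(choose_reference_cluster(d, "y1"), "cl2")
  # single cluster: that cluster
  d1 <- toy_trial(sizes = 4, arms = 0)
  expect_equal(choose_reference_cluster(d1, "y1"), "cl1")
  # equidistant means 18 and 24 around arm mean 21: first-appearing wins
  d2 <- toy_trial(sizes = c(3, 3), arms = c(0, 0),
                  y1 = c(18, 18, 18, 24, 24, 24), y2 = rep(1, 6))
  expect_equal(choose_reference_cluster(d2, "y1"), "cl1")
  expect_error(choose_reference_cluster(dplyr::mutate(d2, y2 = NA_real_),
                                        "y2"),
               "no observed values")
})

test_that("FMI imputations track their own cluster's mean", {
  set.seed(51)
  d <- toy_trial(sizes = c(10, 10, 5, 5), arms = c(0, 0, 1, 1),
                 y1 = c(rnorm(10, 0, 0.1), rnorm(10, 100, 0.1),
                        rnorm(10, 50, 0.1)),
                 y2 = rnorm(30, 5, 0.1), x = rnorm(30))
  d$y1[c(1, 2, 11, 12)] <- NA
  d <- validate_trial(d)
  st <- impute_fmi(d, M = 5, seed = 52)
  imp <- dplyr::filter(st, r1 == 1)
  expect_true(all(abs(imp$y1[imp$cluster_id == "cl1"] - 0) < 5))
  expect_true(all(abs(imp$y1[imp$cluster_id == "cl2"] - 100) < 5))
})

test_that("FMI imputes fully missing clusters from the reference cluster", {
  set.seed(61)
  # arm 0: a large cluster with mean 24 (closest to the arm mean of ~27,
  # hence the reference), a small one at 36, and a third cluster with both
  # outcomes entirely missing
  d <- toy_trial(sizes = c(18, 6, 12, 6, 6), arms = c(0, 0, 0, 1, 1),
                 y1 = c(rnorm(18, 24, 1), rnorm(6, 36, 1), rep(0, 12),
                        rnorm(12, 10, 1)),
                 y2 = rnorm(48, 5, 1), x = rnorm(48))
  d$y1[25:36] <- NA
  d$y2[25:36] <- NA
  d <- validate_trial(d)
  st <- impute_fmi(d, M = 400, seed = 62)
  imp_mean <- mean(st$y1[st$cluster_id == "cl3"])
  # predictive mean equals the reference cluster's fitted mean (about 24)
  expect_true(abs(imp_mean - 24) < 1.5)
  expect_true(abs(imp_mean - 36) > 3)
})

test_that("FMI rejects cluster-level auxiliaries", {
  dm <- masked_fixture()
  expect_error(impute_fmi(dm, M = 2, aux = c("x", "w")),
               "cluster-level covariate")
})

test_that("imputation streams are reproducible and extendable in M", {
  dm <- masked_fixture()
  a <- impute_smi(dm, M = 5, seed = 71)
  b <- impute_smi(dm, M = 5, seed = 71)
  expect_identical(a$y1, b$y1)
  # first 3 imputations of a larger run equal the smaller run
  c3 <- impute_smi(dm, M = 3, seed = 71)
  expect_identical(c3$y1, a$y1[a$.imp <= 3])
})
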