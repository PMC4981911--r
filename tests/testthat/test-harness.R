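test_that("the factorial grid expands to the full design", {
  g <- expand_scenarios()
  expect_equal(nrow(g), 192) # 3 x 4 x 2 x 2 x 4
  expect_equal(length(unique(g$seed)), 192)
  expect_s3_class(g$scenario[[1]], "crt_scenario")

  g1 <- expand_scenarios(designs = list(one = list(J = 25,
                                                   sizes = fixed_sizes(10))),
                         icc_pairs = list(low = c(0.01, 0.01)),
                         eta_levels = "low", response_patterns = "equal",
                         mechanisms = "individual")
  expect_equal(nrow(g1), 1)

  g64 <- expand_scenarios(designs = list(one = list(J = 5,
                                                    sizes = fixed_sizes(50))))
  expect_equal(nrow(g64), 64)

  # differential scenarios carry arm-specific etas; the rest do not
  gd <- expand_scenarios(mechanisms = "differential", eta_levels = "high")
  expect_equal(gd$scenario[[1]]$mechanism$eta_x, c(1.5, 3))
  gi <- expand_scenarios(mechanisms = "cluster", eta_levels = "high")
  expect_equal(gi$scenario[[1]]$mechanism$eta_w, c(2, 2))

  expect_error(expand_scenarios(mechanisms = character(0)), "at least one")
})

test_that("performance metrics follow their definitions", {
  expect_equal(coverage(c(0, 2), c(2, 3), truth = 1), 50)
  expect_equal(coverage(c(0, 0), c(2, 2), truth = 1), 100)
  # closed endpoints: truth on a limit counts as covered
  expect_equal(coverage(1, 2, truth = 1), 100)
  expect_equal(coverage(1, 2, truth = 2), 100)

  bm <- bias_metrics(c(119, 121), truth = 120)
  expect_equal(bm$bias, 0)
  expect_equal(bm$rmse, 1)
  expect_equal(bias_metrics(rep(90, 4), truth = 120)$percent_bias, -25)
  expect_equal(bias_metrics(120, truth = 120),
               tibble::tibble(bias = 0, percent_bias = 0, rmse = 0))
  expect_true(is.na(bias_metrics(c(1, 2), truth = 0)$percent_bias))

  expect_equal(avg_ci_width(c(0, 1), c(2, 5)), 3)
  expect_equal(avg_ci_width(c(2, 2), c(7, 7)), 5)
  expect_equal(avg_ci_width(c(1, 2), c(1, 2)), 0)

  # rmse >= |bias| always
  set.seed(161)
  for (i in 1:10) {
    e <- rnorm(7)
    b <- bias_metrics(e, truth = 0.3)
    expect_gte(b$rmse, abs(b$bias))
  }
})

test_that("a replicate is deterministic and degenerates without missingness", {
  sc <- scenario(J = 6, sizes = fixed_sizes(10),
                 mechanism = mar_mechanism("individual", eta = 1))
  ctl <- gibbs_control(50, 10)
  r1 <- run_replicate(sc, seed = 7, control = ctl)
  r2 <- run_replicate(sc, seed = 7, control = ctl)
  expect_identical(r1, r2)

  # a method subset does not change the other methods' streams
  r_cca <- run_replicate(sc, methods = "cca", seed = 7)
  expect_equal(r_cca$estimate,
               r1$estimate[r1$method == "cca"])

  # zero missingness: every method returns the identical complete-data fit
  sc0 <- scenario(J = 6, sizes = fixed_sizes(10))
  r0 <- run_replicate(sc0, seed = 8, control = ctl)
  est <- matrix(r0$estimate, nrow = 2)
  expect_true(all(abs(est - est[, 1]) < 1e-8))
  expect_true(all(abs(matrix(r0$std.error, 2) - r0$std.error[1:2]) < 1e-8))
})

test_that("complete-case analysis is biased downward under differential missingness", {
  sc <- scenario(J = 25, sizes = fixed_sizes(10),
                 mechanism = mar_mechanism("differential", eta = c(1, 2)))
  sc$mechanism <- calibrate_mechanism(sc$mechanism)
  est <- vapply(1:40, function(i) {
    r <- run_replicate(sc, methods = "cca", seed = derive_seed(1000, i))
    r$estimate[r$term == "beta1"]
  }, numeric(1))
  # one-sided: the mean estimate sits well below the true effect of 120
  expect_lt(mean(est) + 3 * sd(est) / sqrt(length(est)), 120)
})

test_that("run_scenario summarises coverage, bias and widths per method", {
  sc <- scenario(J = 6, sizes = fixed_sizes(10))
  s1 <- run_scenario(sc, n_reps = 1, methods = "cca", seed = 3,
                     keep_replicates = TRUE)
  expect_true(all(s1$coverage_pct %in% c(0, 100)))
  raw <- attr(s1, "replicates")
  expect_equal(s1$avg_ci_width[1],
               raw$conf.high[1] - raw$conf.low[1])

  sc2 <- scenario(J = 8, sizes = fixed_sizes(8),
                  mechanism = mar_mechanism("individual", eta = 1))
  s <- run_scenario(sc2, n_reps = 4, methods = c("cca", "smi"), seed = 4,
                    keep_replicates = TRUE)
  expect_equal(nrow(s), 4) # 2 methods x 2 estimands
  expect_true(all(s$n_replicates == 4))
  expect_true(all(s$rmse >= abs(s$bias) - 1e-12))
  expect_true(all(s$coverage_pct >= 0 & s$coverage_pct <= 100))
  # scenario seeds make the whole grid cell reproducible
  s_again <- run_scenario(sc2, n_reps = 4, methods = c("cca", "smi"),
                          seed = 4)
  expect_equal(s_again$coverage_pct, s$coverage_pct)
  expect_equal(s_again$bias, s$bias)
  expect_equal(s_again$avg_ci_width, s$avg_ci_width)
})

test_that("autoplot produces the coverage and bias views", {
  sc <- scenario(J = 6, sizes = fixed_sizes(10))
  s <- run_scenario(sc, n_reps = 2, methods = "cca", seed = 5)
  p1 <- autoplot(s)
  p2 <- autoplot(s, metric = "bias")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  p3 <- autoplot(inb(-0.05, 100, matrix(c(1e4, 0, 0, 0.0025), 2),
                     lambda = seq(0, 4e4, 1e4)))
  expect_s3_class(p3, "ggplot")
})
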