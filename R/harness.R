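#' Expand the factorial simulation grid
#'
#' Builds the Cartesian product of the design factors: three cluster designs
#' (many small clusters J = 25 of 10; few large J = 5 of 50; unbalanced
#' J = 15 with Gamma-distributed sizes of mean 20 and cv 0.5), four ICC
#' pairs, two covariate-missingness association strengths, two non-response
#' patterns, and four MAR mechanisms. The full default grid has
#' 3 x 4 x 2 x 2 x 4 = 192 scenarios, each with its own derived seed;
#' restrict any factor to run a subset.
#'
#' For the differential-by-treatment mechanism the association strengths are
#' arm-specific: low is `eta = 1` (control) vs `2` (intervention), high is
#' `1.5` vs `3`; the non-response targets are calibrated in the control arm
#' and intervention rates are emergent.
#'
#' @param designs Named list of `list(J =, sizes =)` design settings.
#' @param icc_pairs Named list of `c(icc1, icc2)` pairs.
#' @param eta_levels Subset of `c("low", "high")`.
#' @param response_patterns Subset of `c("equal", "different")` (20%/20% vs
#'   30%/10% target non-response).
#' @param mechanisms Subset of
#'   `c("individual", "cluster", "both", "differential")`.
#' @param M Imputations per scenario.
#' @param seed Master seed; per-scenario seeds are derived from it.
#' @return A tibble with one row per scenario: the factor labels, `J`,
#'   `icc1`, `icc2`, the per-scenario `seed`, and a `scenario` list-column of
#'   [scenario()] objects.
#' @examples
#' nrow(expand_scenarios()) # 192
#' expand_scenarios(mechanisms = "differential", eta_levels = "low")
#' @export
expand_scenarios <- function(designs = NULL, icc_pairs = NULL,
                             eta_levels = c("low", "high"),
                             response_patterns = c("equal", "different"),
                             mechanisms = c("individual", "cluster", "both",
                                            "differential"),
                             M = 10, seed = 1) {
  designs <- designs %||% list(
    many_small = list(J = 25, sizes = fixed_sizes(10)),
    few_large = list(J = 5, sizes = fixed_sizes(50)),
    unbalanced = list(J = 15, sizes = gamma_sizes(20, 0.5))
  )
  icc_pairs <- icc_pairs %||% list(
    low = c(0.01, 0.01), moderate = c(0.20, 0.05),
    high = c(0.20, 0.20), differential = c(0.60, 0.01)
  )
  if (length(designs) == 0 || length(icc_pairs) == 0 ||
      length(eta_levels) == 0 || length(response_patterns) == 0 ||
      length(mechanisms) == 0) {
    abort("every factor needs at least one level")
  }
  eta_levels <- match.arg(eta_levels, c("low", "high"), several.ok = TRUE)
  response_patterns <- match.arg(response_patterns, c("equal", "different"),
                                 several.ok = TRUE)
  mechanisms <- match.arg(mechanisms,
                          c("individual", "cluster", "both", "differential"),
                          several.ok = TRUE)

  grid <- tidyr::expand_grid(
    design = names(designs),
    icc = names(icc_pairs),
    eta_level = eta_levels,
    pattern = response_patterns,
    mechanism = mechanisms
  )
  grid$scenario_id <- seq_len(nrow(grid))
  grid$seed <- vapply(grid$scenario_id, function(i) derive_seed(seed, i),
                      integer(1))
  grid$J <- vapply(grid$design, function(d) as.integer(designs[[d]]$J),
                   integer(1))
  grid$icc1 <- vapply(grid$icc, function(i) icc_pairs[[i]][1], numeric(1))
  grid$icc2 <- vapply(grid$icc, function(i) icc_pairs[[i]][2], numeric(1))
  grid$scenario <- purrr::pmap(grid, function(design, icc, eta_level, pattern,
                                              mechanism, seed, ...) {
    targets <- if (pattern == "equal") c(0.2, 0.2) else c(0.3, 0.1)
    eta <- if (mechanism == "differential") {
      if (eta_level == "low") c(1, 2) else c(1.5, 3)
    } else {
      if (eta_level == "low") 1 else 2
    }
    scenario(J = designs[[design]]$J, sizes = designs[[design]]$sizes,
             icc1 = icc_pairs[[icc]][1], icc2 = icc_pairs[[icc]][2],
             mechanism = mar_mechanism(mechanism, eta = eta,
                                       targets = targets),
             M = M, seed = seed)
  })
  grid[, c("scenario_id", "design", "icc", "eta_level", "pattern", "mechanism",
           "J", "icc1", "icc2", "seed", "scenario")]
}

# Minimal fit wrapper used inside replicate loops: same compiled fit as
# fit_bivariate_mixed(), skipping re-validation of each completed copy.
fit_light <- function(y, cl, arm_cl, reml) {
  f <- fit_bvmm_core(y, cl, arm_cl, reml)
  structure(list(beta = as.numeric(f$beta), vcov_treat = f$vcov_treat,
                 converged = isTRUE(f$converged)),
            class = "crt_bvmm")
}

#' Run one replicate of the simulation pipeline
#'
#' Executes generate -> mask -> handle -> fit -> pool for one dataset. All
#' requested methods consume the identical masked dataset (paired
#' comparison); `"cca"` fits the complete cases directly, the MI methods
#' impute `M` times, fit each completed copy and pool by Rubin's rules with
#' normal confidence intervals.
#'
#' @param scenario A [scenario()] whose `mechanism` is set (or `NULL` for no
#'   missingness).
#' @param methods Subset of `c("cca", "smi", "fmi", "mmi")`.
#' @param seed Replicate seed; generation, masking and each engine draw from
#'   separate derived child streams.
#' @param level Confidence level.
#' @param control [gibbs_control()] for the multilevel engine.
#' @param reml Criterion for the substantive-model fits.
#' @return A tibble with one row per method x estimand: `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `converged`.
#' @export
run_replicate <- function(scenario, methods = c("cca", "smi", "fmi", "mmi"),
                          seed = NULL, level = 0.95,
                          control = gibbs_control(), reml = TRUE) {
  methods <- match.arg(methods, c("cca", "smi", "fmi", "mmi"),
                       several.ok = TRUE)
  seed <- seed %||% sample.int(2147483646, 1)
  mech <- scenario$mechanism
  if (!is.null(mech) && is.null(mech$alpha0)) mech <- calibrate_mechanism(mech)

  d0 <- generate_trial(scenario, seed = derive_seed(seed, 1))
  dm <- if (is.null(mech)) d0 else {
    apply_missingness(d0, mech, seed = derive_seed(seed, 2))
  }
  n <- nrow(dm)
  cl <- match(dm$cluster_id, unique(dm$cluster_id))
  arm_cl <- vapply(split(dm$arm, cl), `[`, integer(1), 1)
  M <- scenario$M
  z <- z_crit(level)

  rows <- vector("list", length(methods))
  for (mi in seq_along(methods)) {
    method <- methods[mi]
    res <- tryCatch({
      if (method == "cca") {
        cc <- complete_cases(dm)
        ccl <- match(cc$cluster_id, unique(cc$cluster_id))
        f <- fit_light(cbind(cc$y1, cc$y2), ccl,
                       vapply(split(cc$arm, ccl), `[`, integer(1), 1), reml)
        se <- sqrt(diag(f$vcov_treat))
        list(est = f$beta, se = se, conv = f$converged)
      } else {
        eng_seed <- derive_seed(seed, 10 + mi)
        stack <- switch(method,
          smi = impute_smi(dm, M = M, seed = eng_seed),
          fmi = impute_fmi(dm, M = M, seed = eng_seed),
          mmi = impute_mmi(dm, M = M, control = control, seed = eng_seed))
        fits <- lapply(seq_len(M), function(m) {
          idx <- ((m - 1) * n + 1):(m * n)
          fit_light(cbind(stack$y1[idx], stack$y2[idx]), cl, arm_cl, reml)
        })
        conv <- vapply(fits, function(f) f$converged, logical(1))
        if (sum(conv) < 2) stop("fewer than 2 converged imputation fits")
        pooled <- suppressWarnings(rubin_pool(fits, level = level))
        list(est = pooled$estimate, se = pooled$std.error, conv = all(conv))
      }
    }, error = function(e) e)
    rows[[mi]] <- if (inherits(res, "error")) {
      tibble::tibble(method = method, term = c("beta1", "beta2"),
                     estimate = NA_real_, std.error = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     converged = FALSE, error = conditionMessage(res))
    } else {
      tibble::tibble(method = method, term = c("beta1", "beta2"),
                     estimate = res$est, std.error = res$se,
                     conf.low = res$est - z * res$se,
                     conf.high = res$est + z * res$se,
                     converged = res$conv, error = NA_character_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run a full scenario and summarise performance
#'
#' Repeats [run_replicate()] `n_reps` times (replicate `i` uses the child
#' seed derived from `seed` and `i`, so any replicate can be reproduced in
#' isolation) and summarises each method x estimand: coverage of the true
#' treatment effects, empirical and percent bias, RMSE, average CI width,
#' and the Monte Carlo standard error of the coverage. Replicates whose fit
#' failed or did not converge are excluded for that method and counted in
#' `n_excluded`; a method losing more than 10% of replicates is flagged.
#'
#' @inheritParams run_replicate
#' @param n_reps Number of replicate datasets.
#' @param seed Master seed for the scenario run.
#' @param keep_replicates Attach the raw per-replicate results as an
#'   attribute (`"replicates"`).
#' @return A `crt_performance` tibble: one row per method x estimand with
#'   `coverage_pct`, `bias`, `percent_bias`, `rmse`, `avg_ci_width`,
#'   `n_replicates`, `n_excluded`, `mc_se_coverage`, `flagged`.
#' @examples
#' sc <- scenario(J = 6, sizes = fixed_sizes(10),
#'                mechanism = mar_mechanism("individual", eta = 1))
#' run_scenario(sc, n_reps = 5, methods = "cca", seed = 1)
#' @export
run_scenario <- function(scenario, n_reps = 1000,
                         methods = c("cca", "smi", "fmi", "mmi"), seed = 1,
                         level = 0.95, control = gibbs_control(),
                         reml = TRUE, keep_replicates = FALSE) {
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  mech <- scenario$mechanism
  if (!is.null(mech) && is.null(mech$alpha0)) {
    scenario$mechanism <- calibrate_mechanism(mech)
  }
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    r <- run_replicate(scenario, methods = methods,
                       seed = derive_seed(seed, i), level = level,
                       control = control, reml = reml)
    r$replicate <- i
    reps[[i]] <- r
  }
  raw <- dplyr::bind_rows(reps)
  truth <- c(beta1 = scenario$effect1, beta2 = scenario$effect2)

  summ <- raw |>
    dplyr::group_by(.data$method, .data$term) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_excluded = sum(!.data$converged | is.na(.data$estimate)),
      .groups = "drop_last"
    ) |>
    dplyr::ungroup()
  ok <- raw[raw$converged & !is.na(raw$estimate), , drop = FALSE]
  stats <- ok |>
    dplyr::group_by(.data$method, .data$term) |>
    dplyr::summarise(
      coverage_pct = coverage(.data$conf.low, .data$conf.high,
                              truth[.data$term[1]]),
      bias = mean(.data$estimate) - truth[.data$term[1]],
      percent_bias = 100 * (mean(.data$estimate) - truth[.data$term[1]]) /
        truth[.data$term[1]],
      rmse = sqrt(mean((.data$estimate - truth[.data$term[1]])^2)),
      avg_ci_width = avg_ci_width(.data$conf.low, .data$conf.high),
      .groups = "drop"
    )
  out <- dplyr::left_join(summ, stats, by = c("method", "term"))
  out$mc_se_coverage <- 100 * sqrt(
    (out$coverage_pct / 100) * (1 - out$coverage_pct / 100) /
      pmax(out$n_replicates - out$n_excluded, 1))
  out$flagged <- out$n_excluded > 0.1 * out$n_replicates
  out$method <- factor(out$method, levels = c("cca", "smi", "fmi", "mmi"))
  out <- dplyr::arrange(out, .data$method, .data$term)
  out$method <- as.character(out$method)
  class(out) <- c("crt_performance", class(out))
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  attr(out, "alpha0") <- if (is.null(scenario$mechanism)) NULL else
    scenario$mechanism$alpha0
  if (keep_replicates) attr(out, "replicates") <- raw
  out
}
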