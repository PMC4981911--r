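#' Choose the reference cluster for fixed-effects imputation
#'
#' With fixed cluster effects, clusters whose outcomes are entirely missing
#' are imputed from the reference cluster's distribution, so the reference
#' should be representative: this returns the cluster whose observed-outcome
#' mean is closest to the arm mean. With `outcome = "combined"` the distances
#' of the two outcomes are standardised (divided by the arm-level SD of the
#' observed values) and summed. Ties go to the first-appearing cluster.
#'
#' @param data_arm Records of a single treatment arm.
#' @param outcome `"combined"` (default), `"y1"` or `"y2"`.
#' @param candidates Optional subset of cluster ids to choose among.
#' @return The reference `cluster_id` (a string).
#' @export
choose_reference_cluster <- function(data_arm,
                                     outcome = c("combined", "y1", "y2"),
                                     candidates = NULL) {
  outcome <- match.arg(outcome)
  if (length(unique(data_arm$arm)) != 1) {
    abort("`data_arm` must contain a single treatment arm")
  }
  cls <- unique(data_arm$cluster_id)
  use <- if (outcome == "combined") c("y1", "y2") else outcome
  dist <- setNames(numeric(length(cls)), cls)
  ok <- setNames(rep(TRUE, length(cls)), cls)
  for (l in use) {
    y <- data_arm[[l]]
    obs <- !is.na(y)
    if (!any(obs)) abort(sprintf("no observed values of %s in this arm", l))
    arm_mean <- mean(y[obs])
    scale <- sd(y[obs])
    if (!is.finite(scale) || scale == 0) scale <- 1
    cl_mean <- tapply(y[obs], factor(data_arm$cluster_id[obs], levels = cls),
                      mean)
    ok <- ok & !is.na(cl_mean)
    dist <- dist + abs(cl_mean - arm_mean) / scale
  }
  if (!is.null(candidates)) ok <- ok & cls %in% candidates
  if (!any(ok)) abort("no cluster has observed data for the requested outcome(s)")
  cand <- cls[ok]
  # first-appearance order breaks ties because which.min picks the earliest
  cand[which.min(dist[cand])]
}

#' Fixed-cluster-effects multiple imputation (FMI)
#'
#' As [impute_smi()], but the per-arm imputation model adds an indicator
#' column for every cluster except a reference cluster, so each cluster gets
#' its own fixed intercept shift. The reference is chosen by
#' [choose_reference_cluster()] (nearest to the arm mean) among clusters that
#' contribute complete rows; clusters with no complete rows get no indicator
#' and are therefore imputed from the reference cluster's predictive
#' distribution. Cluster-level covariates cannot enter a fixed-cluster-effects
#' design (they are collinear with the indicators), so `aux` is restricted to
#' individual-level covariates.
#'
#' @inheritParams impute_smi
#' @param aux Individual-level auxiliary covariates (default `"x"`).
#' @return A `crt_imputed` stack of `M` completed copies.
#' @export
impute_fmi <- function(data, M = 10, aux = "x", seed = NULL, cycles = 10) {
  data <- validate_trial(data)
  for (a in aux) {
    if (!a %in% names(data)) abort(sprintf("auxiliary column `%s` not found", a))
    v <- data[[a]]
    within_const <- all(tapply(v, data$cluster_id,
                               function(z) length(unique(z)) == 1))
    if (within_const && length(unique(v)) > 1) {
      abort(sprintf(
        "`%s` is a cluster-level covariate; it cannot be used with fixed cluster effects",
        a))
    }
  }
  design_fun <- function(sub) {
    X <- make_design(sub, aux)
    cc_cls <- unique(sub$cluster_id[sub$r1 == 0L & sub$r2 == 0L])
    if (length(cc_cls) == 0) {
      abort("no cluster in this arm has complete rows; cannot anchor fixed effects")
    }
    ref <- choose_reference_cluster(sub, "combined", candidates = cc_cls)
    dummy_cls <- setdiff(intersect(unique(sub$cluster_id), cc_cls), ref)
    for (cl in dummy_cls) {
      X <- cbind(X, as.numeric(sub$cluster_id == cl))
      colnames(X)[ncol(X)] <- paste0("cluster", cl)
    }
    X
  }
  impute_joint_normal(data, M, design_fun, "fmi", seed)
}
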