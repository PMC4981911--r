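# Gauss-Hermite nodes are cached per session; 80 nodes keep the calibration
# expectation accurate to well below 1e-6 for the |eta| <= 3, rates in
# [0.1, 0.45] regime used here.
.gh_env <- new.env(parent = emptyenv())

gh_nodes <- function(n = 80) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(n)
  .gh_env[[key]]
}

# E[plogis(a + s Z)] with Z standard normal, by Gauss-Hermite quadrature
expit_normal_mean <- function(a, s, n_nodes = 80) {
  gh <- gh_nodes(n_nodes)
  sum(gh$w * plogis(a + s * sqrt(2) * gh$x)) / sqrt(pi)
}

#' Specify a missing-at-random non-response mechanism
#'
#' Each outcome's non-response indicator is Bernoulli with
#' `logit(pi) = alpha0 + eta_x * X + eta_w * W`, depending only on the fully
#' observed covariates (hence MAR by construction). Four kinds are supported:
#' `"individual"` (only `X` enters), `"cluster"` (only `W`), `"both"`, and
#' `"differential"` where the association strengths differ by treatment arm
#' (`eta` is then a length-2 vector `c(control, intervention)`).
#'
#' Intercepts `alpha0` are not supplied directly: they are calibrated by
#' [calibrate_mechanism()] so that the expected non-response proportion hits
#' `targets`. For the differential kind the default calibration mode
#' (`calibrate = "control"`) solves for a single `alpha0` per outcome in the
#' control arm and reuses it with the intervention-arm `eta`, so the
#' intervention-arm rate is emergent; `calibrate = "per_arm"` instead hits
#' `targets` in each arm.
#'
#' @param kind One of `"individual"`, `"cluster"`, `"both"`, `"differential"`.
#' @param eta Association strength; scalar for the first three kinds, length-2
#'   `c(control, intervention)` for `"differential"`.
#' @param targets Length-2 target non-response proportions `c(y1, y2)`.
#' @param calibrate Calibration mode for the differential kind.
#' @return A `crt_mechanism` object (uncalibrated; `alpha0` is `NULL`).
#' @examples
#' mech <- mar_mechanism("differential", eta = c(1, 2), targets = c(0.2, 0.2))
#' calibrate_mechanism(mech)
#' @export
mar_mechanism <- function(kind = c("individual", "cluster", "both", "differential"),
                          eta = 1, targets = c(0.2, 0.2),
                          calibrate = c("control", "per_arm")) {
  kind <- match.arg(kind)
  calibrate <- match.arg(calibrate)
  check_prob(targets, "targets")
  if (length(targets) != 2) abort("`targets` must give one rate per outcome")
  if (kind == "differential") {
    if (length(eta) != 2) {
      abort("differential mechanism needs `eta = c(control, intervention)`")
    }
    eta_x <- eta_w <- as.numeric(eta)
  } else {
    if (length(eta) != 1) abort("`eta` must be a scalar for this kind")
    eta_x <- if (kind %in% c("individual", "both")) rep(eta, 2) else c(0, 0)
    eta_w <- if (kind %in% c("cluster", "both")) rep(eta, 2) else c(0, 0)
  }
  structure(list(kind = kind, eta_x = eta_x, eta_w = eta_w,
                 targets = as.numeric(targets), calibrate = calibrate,
                 alpha0 = NULL),
            class = "crt_mechanism")
}

#' @export
print.crt_mechanism <- function(x, ...) {
  cat(sprintf("<MAR mechanism: %s; eta_x = (%g, %g), eta_w = (%g, %g); targets = (%g, %g)%s>\n",
              x$kind, x$eta_x[1], x$eta_x[2], x$eta_w[1], x$eta_w[2],
              x$targets[1], x$targets[2],
              if (is.null(x$alpha0)) "; uncalibrated" else
                sprintf("; alpha0 y1 = %.4f, y2 = %.4f",
                        x$alpha0[1, 1], x$alpha0[2, 1])))
  invisible(x)
}

#' Calibrate the intercept of a missingness model
#'
#' Solves `E[plogis(alpha0 + eta_x X + eta_w W)] = target` for `alpha0`, with
#' `X`, `W` independent standard normal, so the combined covariate signal is
#' `s Z` with `s^2 = eta_x^2 + eta_w^2`. The expectation is evaluated by
#' 80-node Gauss-Hermite quadrature and inverted with [stats::uniroot()] to
#' `|E - target| < 1e-9`.
#'
#' @param mech A [mar_mechanism()].
#' @param outcome Which outcome (1 or 2) the intercept is for.
#' @param target Target proportion; defaults to the mechanism's stored target.
#' @param arm Arm whose `eta` is used (default 0, the control arm).
#' @return The calibrated intercept `alpha0` (a number).
#' @examples
#' calibrate_alpha0(mar_mechanism("individual", eta = 0), target = 0.2)
#' # = qlogis(0.2) when no covariate enters
#' @export
calibrate_alpha0 <- function(mech, outcome = 1, target = NULL, arm = 0) {
  stopifnot(inherits(mech, "crt_mechanism"))
  target <- target %||% mech$targets[outcome]
  check_prob(target, "target")
  s <- sqrt(mech$eta_x[arm + 1]^2 + mech$eta_w[arm + 1]^2)
  if (s == 0) {
    return(qlogis(target))
  }
  f <- function(a) expit_normal_mean(a, s) - target
  lo <- qlogis(target) - 3 * s - 5
  hi <- qlogis(target) + 3 * s + 5
  uniroot(f, c(lo, hi), tol = 1e-11)$root
}

#' Calibrate all intercepts of a mechanism
#'
#' Fills `alpha0` for both outcomes (and, in `"per_arm"` mode, both arms).
#' In the default mode a single intercept per outcome is calibrated using the
#' control-arm `eta` and shared across arms.
#'
#' @param mech A [mar_mechanism()].
#' @return The mechanism with its `alpha0` matrix (outcome by arm) filled.
#' @export
calibrate_mechanism <- function(mech) {
  stopifnot(inherits(mech, "crt_mechanism"))
  a <- matrix(NA_real_, 2, 2, dimnames = list(c("y1", "y2"), c("arm0", "arm1")))
  for (l in 1:2) {
    if (mech$kind == "differential" && mech$calibrate == "per_arm") {
      for (k in 0:1) a[l, k + 1] <- calibrate_alpha0(mech, l, arm = k)
    } else {
      a[l, ] <- calibrate_alpha0(mech, l, arm = 0)
    }
  }
  mech$alpha0 <- a
  mech
}

#' Linear predictor of the non-response model
#'
#' `alpha0 + eta_x x + eta_w w` on the logit scale, using the arm-specific
#' association strengths (they differ between arms only for the
#' `"differential"` kind) and the calibrated intercept.
#'
#' @param mech A calibrated [mar_mechanism()].
#' @param x,w Covariate values (vectorised).
#' @param arm Arm indicator(s), 0/1.
#' @param outcome Outcome index (1 or 2).
#' @return Logit-scale probabilities of non-response.
#' @export
linear_predictor <- function(mech, x, w, arm, outcome = 1) {
  stopifnot(inherits(mech, "crt_mechanism"))
  if (is.null(mech$alpha0)) {
    abort("mechanism is not calibrated; run calibrate_mechanism() first")
  }
  mech$alpha0[outcome, arm + 1] + mech$eta_x[arm + 1] * x +
    mech$eta_w[arm + 1] * w
}

#' Impose non-response on a complete trial dataset
#'
#' Draws each record's non-response indicators independently per outcome from
#' `Bernoulli(plogis(linear_predictor))` and blanks the selected outcome
#' values. Covariates and arm are never masked, and retained outcome values
#' are untouched.
#'
#' @param data A complete trial data frame (no pre-existing missingness).
#' @param mech A [mar_mechanism()]; calibrated automatically if needed.
#' @param seed Optional seed.
#' @return The trial tibble with missing values and `r1`/`r2` flags set.
#' @export
apply_missingness <- function(data, mech, seed = NULL) {
  data <- validate_trial(data)
  stopifnot(inherits(mech, "crt_mechanism"))
  if (any(data$r1 == 1L | data$r2 == 1L)) {
    abort("`data` already contains missing outcomes")
  }
  if (is.null(mech$alpha0)) mech <- calibrate_mechanism(mech)
  with_seed(seed, {
    n <- nrow(data)
    for (l in 1:2) {
      p <- plogis(linear_predictor(mech, data$x, data$w, data$arm, l))
      r <- rbinom(n, 1L, p)
      ycol <- paste0("y", l)
      rcol <- paste0("r", l)
      data[[ycol]][r == 1L] <- NA_real_
      data[[rcol]] <- as.integer(r)
    }
    data
  })
}
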