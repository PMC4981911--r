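#' Simulation performance metrics
#'
#' `coverage()` is the percentage of (closed) intervals containing the truth;
#' `bias_metrics()` returns the empirical bias `mean(estimate) - truth`, the
#' percent bias `100 * bias / truth` (undefined, `NA`, when the truth is 0)
#' and the root-mean-square error; `avg_ci_width()` is the distance between
#' the average upper and average lower confidence limits.
#'
#' @param lower,upper Vectors of confidence limits.
#' @param truth True parameter value.
#' @param estimates Vector of point estimates.
#' @return `coverage()` and `avg_ci_width()` return a number;
#'   `bias_metrics()` a one-row tibble with `bias`, `percent_bias`, `rmse`.
#' @examples
#' coverage(c(0, 2), c(2, 3), truth = 1) # 50
#' bias_metrics(c(119, 121), truth = 120)
#' avg_ci_width(c(0, 1), c(2, 5)) # 3
#' @export
coverage <- function(lower, upper, truth) {
  if (length(lower) == 0 || length(lower) != length(upper)) {
    abort("`lower` and `upper` must be non-empty vectors of equal length")
  }
  100 * mean(lower <= truth & truth <= upper)
}

#' @rdname coverage
#' @export
bias_metrics <- function(estimates, truth) {
  if (length(estimates) == 0) abort("need at least one estimate")
  b <- mean(estimates) - truth
  tibble::tibble(
    bias = b,
    percent_bias = if (truth == 0) NA_real_ else 100 * b / truth,
    rmse = sqrt(mean((estimates - truth)^2))
  )
}

#' @rdname coverage
#' @export
avg_ci_width <- function(lower, upper) {
  if (length(lower) == 0 || length(lower) != length(upper)) {
    abort("`lower` and `upper` must be non-empty vectors of equal length")
  }
  mean(upper) - mean(lower)
}
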