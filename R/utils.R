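#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus any number of integer indices
#' (scenario number, replicate, arm, imputation, ...) to a new seed in
#' `[1, 2^31 - 2]`. Derived streams let every replicate of a simulation be
#' reproduced in isolation, independently of execution order.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices identifying the child stream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, 3, 2)
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus of the Lehmer generator
  s <- as.double(seed %% m)
  # fold each index in with one multiplicative-congruential step
  for (k in idx) {
    s <- (s * 48271 + as.double(k %% m) + 1) %% m
  }
  as.integer(if (s == 0) 1 else s)
}

# Run code with a temporary RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; with seed = NULL the current stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# draw n correlated standard-normal pairs, then scale by (sd1, sd2)
rbvnorm <- function(n, sd1, sd2, corr) {
  z1 <- rnorm(n)
  z2 <- corr * z1 + sqrt(max(0, 1 - corr^2)) * rnorm(n)
  cbind(sd1 * z1, sd2 * z2)
}

# normal CI half-width multiplier
z_crit <- function(level) qnorm((1 + level) / 2)

check_prob <- function(x, name, open = TRUE) {
  ok <- if (open) x > 0 & x < 1 else x >= 0 & x < 1
  if (!all(is.finite(x)) || !all(ok)) {
    abort(sprintf("`%s` must lie in %s", name, if (open) "(0, 1)" else "[0, 1)"))
  }
  invisible(x)
}
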