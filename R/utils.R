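# Shared numerical helpers and seeding utilities.

# Moment-matching constant for E[sigmoid(x)] under a Gaussian:
# E[s(x)] ~ s(mu / sqrt(1 + C_MM * v)), the standard logistic-probit closure.
C_MM <- 3 / pi^2

#' Logistic sigmoid
#'
#' @param x Numeric vector of log-odds.
#' @return `1 / (1 + exp(-x))`, computed stably for large `|x|`.
#' @keywords internal
sigmoid <- function(x) {
  # plogis is the numerically careful base implementation
  stats::plogis(x)
}

#' Gaussian-smoothed sigmoid
#'
#' Moment-matched approximation to `E[sigmoid(x)]` for `x ~ N(mu, v)`.
#'
#' @param mu Mean of the Gaussian (log-odds scale).
#' @param v Variance (>= 0).
#' @return Approximate expected sigmoid, in (0, 1).
#' @export
smoothed_sigmoid <- function(mu, v) {
  stopifnot(all(is.finite(mu)), all(v >= 0))
  sigmoid(mu / sqrt(1 + C_MM * v))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched (no cross-talk between concurrent runs).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a root seed
#'
#' Counter-based derivation so that Monte-Carlo repetitions (and pairs of
#' phenotypes within a tournament) get independent, reproducible streams that
#' do not depend on execution order.
#'
#' @param root Integer root seed.
#' @param ... One or more non-negative integer counters (e.g. pair index,
#'   repetition index).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(root, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(root) %% m
  for (i in idx) {
    # LCG-style mix; doubles hold these products exactly (< 2^53)
    s <- (s * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(s)
}

# Stop with a message naming the offending config/argument field.
fail_field <- function(path, msg) {
  stop(sprintf("%s: %s", path, msg), call. = FALSE)
}
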