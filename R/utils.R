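# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Reproducibility with module independence: every stochastic stage draws its
#' own seed from the master seed through this splitting rule, so that changing
#' one stage's sampling does not perturb another's.  The rule is
#' `(seed * 48271 + 97 * stream) mod (2^31 - 1)`, kept strictly below 2^31 so
#' the result is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param stream nonnegative integer stream index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + 97 * as.numeric(stream)) %% m)
}

#' @keywords internal
rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) { # numerically possible for tiny alpha
    x[sample.int(length(alpha), 1L)] <- 1
  }
  x / sum(x)
}

#' @keywords internal
is_simplex <- function(p, tol = 1e-9) {
  is.numeric(p) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

#' @keywords internal
stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
}

#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
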