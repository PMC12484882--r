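# Internal numeric helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; keeps all
# derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483629) + 1L
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_norms <- function(m) sqrt(rowSums(m * m))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a uniformly random 3D rotation matrix
#'
#' QR-based Haar sampling; the returned matrix has determinant +1.
#'
#' @param seed optional integer seed for reproducibility.
#' @return a 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Stable softmax for a vector or for each row of a matrix.
softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

softmax_rows <- function(x) {
  z <- exp(x - apply(x, 1L, max))
  z / rowSums(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
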