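# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. All exported stochastic operations route through this, so
# the package never leaves global RNG state behind.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds derived from one master seed; kept below 2^31.
child_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_norm <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / nrm
}

# Symmetric inverse square root with an optional ridge; used to whiten the
# noise covariance before the eigendecomposition.
inv_sqrt_sym <- function(m, ridge_rel = 1e-8) {
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  d <- eg$values
  tol <- max(d, 0) * 1e-10
  if (any(d <= tol)) {
    eps <- ridge_rel * sum(diag(m)) / nrow(m)
    if (eps <= 0) eps <- ridge_rel
    d <- d + eps
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(d))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
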