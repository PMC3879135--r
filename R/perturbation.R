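#' Drop one unit from a weight vector
#'
#' Sets the weight of one unit to zero and renormalizes (the
#' discriminability `A` is norm-invariant). Equivalent to removing the unit
#' from the population while keeping the remaining weights.
#'
#' @param w A [weight_vector] with N >= 2.
#' @param unit Index of the unit to drop.
#' @return A unit-norm [weight_vector].
#' @export
drop_unit <- function(w, unit) {
  v <- if (inherits(w, "weight_vector")) w$weights else as.numeric(w)
  if (length(v) < 2)
    stop("cannot drop a unit from a single-neuron population", call. = FALSE)
  unit <- as.integer(unit)
  if (unit < 1 || unit > length(v)) stop("invalid unit index", call. = FALSE)
  v[unit] <- 0
  if (all(v == 0))
    stop("dropping this unit leaves a zero weight vector", call. = FALSE)
  weight_vector(v, scheme = "custom")
}

#' Orthonormalized eigenbasis of the decoding problem
#'
#' The generalized eigenvectors of (signal covariance, noise covariance)
#' rank the directions of population activity by their signal-to-noise
#' ratio, but they are not mutually orthogonal (the whitened problem is
#' symmetric; the mapped-back vectors are not). For a well-defined notion
#' of rotation angle, the eigenvectors are orthonormalized by the
#' Gram-Schmidt procedure in descending-eigenvalue order, so the first
#' basis vector is exactly the optimal decoding direction and each later
#' vector spans the most informative remaining dimension. Directions lost
#' to rank deficiency (or inactive neurons) are completed arbitrarily
#' within the remaining subspace.
#'
#' @param decomp A [cov_decompose] result.
#' @return An N x N matrix with orthonormal columns; column 1 is the
#'   groupwise-optimal direction. Pairwise inner products are below 1e-10.
#' @export
orthogonalized_eigenbasis <- function(decomp) {
  act <- decomp$active_mask
  n <- length(act)
  sig <- decomp$signal_cov[act, act, drop = FALSE]
  noi <- decomp$noise_cov[act, act, drop = FALSE]
  wm <- inv_sqrt_sym(noi)
  m <- wm %*% sig %*% wm
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vecs_a <- wm %*% eg$vectors          # generalized eigenvectors, descending
  vecs <- matrix(0, n, sum(act))
  vecs[act, ] <- vecs_a
  basis <- matrix(0, n, 0)
  for (k in seq_len(ncol(vecs))) {
    v <- vecs[, k]
    if (ncol(basis) > 0) v <- v - basis %*% crossprod(basis, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10 * sqrt(sum(vecs[, k]^2)))
      basis <- cbind(basis, v / nv)
  }
  # complete the basis (inactive neurons / rank-deficient directions)
  if (ncol(basis) < n) {
    for (k in seq_len(n)) {
      if (ncol(basis) == n) break
      v <- diag(n)[, k]
      v <- v - basis %*% crossprod(basis, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) basis <- cbind(basis, v / nv)
    }
  }
  # align column 1 with the canonical optimal direction
  w1 <- rep(0, n)
  w1[act] <- vecs_a[, 1]
  w1 <- canonical_sign(unit_norm(w1), decomp$per_stimulus_mean)
  if (sum(basis[, 1] * w1) < 0) basis[, 1] <- -basis[, 1]
  basis
}

#' Rotate a weight vector toward a target direction
#'
#' Great-circle rotation confined to the 2-plane spanned by `w` and
#' `direction`: components orthogonal to that plane are unchanged, and the
#' angle is measured from `w` (positive toward `direction`).
#'
#' @param w A [weight_vector] or unit vector.
#' @param direction Target direction (need not be orthogonal to `w`, but
#'   must not be parallel to it).
#' @param angle_deg Rotation angle in degrees.
#' @return A unit-norm [weight_vector].
#' @export
rotate_weights <- function(w, direction, angle_deg) {
  v <- unit_norm(if (inherits(w, "weight_vector")) w$weights else as.numeric(w))
  d <- unit_norm(if (inherits(direction, "weight_vector"))
    direction$weights else as.numeric(direction))
  if (length(d) != length(v)) stop("dimension mismatch", call. = FALSE)
  perp <- d - sum(d * v) * v
  np <- sqrt(sum(perp^2))
  if (np < 1e-12)
    stop("`direction` is parallel to `w`; the rotation plane is undefined",
         call. = FALSE)
  u2 <- perp / np
  th <- deg2rad(angle_deg)
  weight_vector(cos(th) * v + sin(th) * u2, scheme = "custom")
}

#' Rotation trajectory from the optimal direction to the identity line
#'
#' Rotates the optimal weight vector toward the pooling direction (the
#' identity line) along the two asymmetric great-circle arcs that together
#' cover the full 180 degrees separating the identity direction from its
#' negative. Because the optimal direction is generally not perpendicular
#' to the identity line, one path is shorter than the other; the endpoint
#' of each path is collinear with the identity line, so its performance
#' equals pooling's `A` exactly. Angles are sampled every `step_deg`
#' degrees plus the exact endpoint.
#'
#' @param recording A [population_recording].
#' @param w_opt The optimal [weight_vector] (e.g. [groupwise_optimal]).
#' @param step_deg Angular step in degrees (default 10).
#' @return A data frame of class `rotation_trajectory` with columns
#'   `path` (`"short"`/`"long"`), `angle_deg` (deviation from optimal,
#'   signed by path direction), `average_A`, and `relative_A`
#'   (`average_A / average_A(0)`).
#' @export
rotation_toward_identity <- function(recording, w_opt, step_deg = 10) {
  n <- n_neurons(recording)
  if (n < 2) stop("need at least two neurons", call. = FALSE)
  v <- unit_norm(if (inherits(w_opt, "weight_vector")) w_opt$weights
                 else as.numeric(w_opt))
  ident <- rep(1, n) / sqrt(n)
  cosang <- clamp(sum(v * ident), -1, 1)
  theta0 <- rad2deg(acos(cosang))       # short-path length toward +identity
  if (theta0 < 1e-8 || 180 - theta0 < 1e-8) {
    # optimal lies on the identity line: single degenerate flat path
    a0 <- average_a(recording, v)
    out <- data.frame(path = "short", angle_deg = 0,
                      average_A = a0, relative_A = 1)
    class(out) <- c("rotation_trajectory", "data.frame")
    return(out)
  }
  a0 <- average_a(recording, v)
  angles_short <- unique(c(seq(0, theta0, by = step_deg), theta0))
  angles_long <- unique(c(seq(0, 180 - theta0, by = step_deg), 180 - theta0))
  # endpoints are collinear with the identity line; evaluate them with the
  # exact identity vector so they match pooling bit-for-bit
  eval_path <- function(angles, sign) {
    end <- angles[length(angles)]
    vapply(angles, function(th) {
      if (th == end && th > 0) average_a(recording, ident)
      else average_a(recording, rotate_weights(v, ident, sign * th))
    }, numeric(1))
  }
  a_short <- eval_path(angles_short, 1)   # toward +identity
  a_long <- eval_path(angles_long, -1)    # away, ending at -identity
  out <- data.frame(
    path = rep(c("short", "long"), c(length(angles_short), length(angles_long))),
    angle_deg = c(angles_short, -angles_long),
    average_A = c(a_short, a_long),
    relative_A = c(a_short, a_long) / a0)
  class(out) <- c("rotation_trajectory", "data.frame")
  out
}

#' Rotation trajectories toward each eigen-dimension of the decoding problem
#'
#' Rotates the optimal direction toward each other eigen-dimension and
#' records the average discriminability along each trajectory. The rotation
#' is performed in the noise-whitened coordinates, where the eigenvectors
#' of the decoding problem form an orthonormal basis and the angle is
#' well-defined; the rotated direction is mapped back to neuron space
#' before decoding. In these coordinates the signal-to-noise ratio along a
#' deviation of angle `theta` toward dimension `k` is exactly
#' `cos^2(theta) lambda_1 + sin^2(theta) lambda_k`, so the performance cost
#' at any angle is ordered by the eigenvalue of the target dimension:
#' deviations toward more informative dimensions cost less.
#'
#' @param recording A [population_recording].
#' @param decomp Optional precomputed [cov_decompose] result.
#' @param angles_deg Deviation angles to evaluate (degrees, in whitened
#'   coordinates).
#' @return A data frame with columns `dimension` (2..N, by descending
#'   eigenvalue), `angle_deg`, `average_A`, `relative_A`.
#' @export
rotation_toward_dimensions <- function(recording, decomp = NULL,
                                       angles_deg = seq(0, 90, by = 10)) {
  decomp <- decomp %||% cov_decompose(recording)
  act <- decomp$active_mask
  n <- length(act)
  sig <- decomp$signal_cov[act, act, drop = FALSE]
  noi <- decomp$noise_cov[act, act, drop = FALSE]
  wm <- inv_sqrt_sym(noi)
  m <- wm %*% sig %*% wm
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  back <- function(u) {          # whitened direction -> neuron-space weights
    w <- rep(0, n); w[act] <- as.numeric(wm %*% u)
    unit_norm(w)
  }
  a0 <- average_a(recording, back(eg$vectors[, 1]))
  rows <- list()
  for (k in 2:ncol(eg$vectors)) {
    a <- vapply(angles_deg, function(th) {
      if (th == 0) return(a0)
      u <- cos(deg2rad(th)) * eg$vectors[, 1] +
        sin(deg2rad(th)) * eg$vectors[, k]
      average_a(recording, back(u))
    }, numeric(1))
    rows[[k - 1L]] <- data.frame(dimension = k, angle_deg = angles_deg,
                                 average_A = a, relative_A = a / a0)
  }
  do.call(rbind, rows)
}

#' Angle between two weight vectors
#'
#' The inverse cosine of the dot product of the unit-norm weights, in
#' degrees. Weight vectors produced by the fitters are sign-canonicalized,
#' so matched decoders yield small angles.
#'
#' @param w1,w2 [weight_vector]s or numeric vectors (non-zero).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_difference <- function(w1, w2) {
  v1 <- unit_norm(if (inherits(w1, "weight_vector")) w1$weights else as.numeric(w1))
  v2 <- unit_norm(if (inherits(w2, "weight_vector")) w2$weights else as.numeric(w2))
  if (length(v1) != length(v2)) stop("dimension mismatch", call. = FALSE)
  rad2deg(acos(clamp(sum(v1 * v2), -1, 1)))
}

# Random complementary half-split of the trials; returns list(train, test).
half_split <- function(t) {
  idx <- sample.int(t, t %/% 2)
  list(train = sort(idx), test = sort(setdiff(seq_len(t), idx)))
}

#' Estimation bias of the angular difference from finite trials
#'
#' The angle between weight vectors fitted on complementary random
#' trial-halves of the *same* recording is positive even when the true
#' optimal direction is fixed; its mean over random splits estimates the
#' positive bias to subtract from cross-state angular differences.
#'
#' @param recording A [population_recording] with an even trial count.
#' @param scheme Decoding scheme fitted on each half.
#' @param n_splits Number of random half-splits (100 in the canonical
#'   design).
#' @param seed Integer seed.
#' @return Mean angle in degrees across splits.
#' @export
split_half_bias <- function(recording, scheme = "groupwise_optimal",
                            n_splits = 100, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  t <- n_trials(recording)
  seeds <- child_seeds(seed, n_splits)
  ang <- vapply(seeds, function(sd) {
    sp <- with_seed(sd, half_split(t))
    w1 <- fit_decoder(subset_trials(recording, sp$train), scheme)
    w2 <- fit_decoder(subset_trials(recording, sp$test), scheme)
    angular_difference(w1, w2)
  }, numeric(1))
  mean(ang)
}

#' Split-half generalization of a decoding scheme
#'
#' Fits the scheme on a random half of the trials and evaluates the average
#' discriminability on both halves; returns the mean over splits of
#' `A(test) / A(train)`. Values near 1 mean the weights generalize to
#' unseen trials.
#'
#' @inheritParams split_half_bias
#' @return A list with `ratio` (mean A_test/A_train), `a_train`, `a_test`
#'   (per-split vectors), and `degenerate` (TRUE if any training A was 0,
#'   in which case those splits are dropped from the ratio).
#' @export
split_half_generalization <- function(recording, scheme = "groupwise_optimal",
                                      n_splits = 100, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_splits < 1) stop("n_splits must be >= 1", call. = FALSE)
  t <- n_trials(recording)
  if (t %% 2 != 0) stop("trial count must be even", call. = FALSE)
  seeds <- child_seeds(seed, n_splits)
  a_train <- a_test <- numeric(n_splits)
  for (k in seq_len(n_splits)) {
    sp <- with_seed(seeds[k], half_split(t))
    train <- subset_trials(recording, sp$train)
    test <- subset_trials(recording, sp$test)
    w <- fit_decoder(train, scheme)
    a_train[k] <- discriminability(train, w)$average_A
    a_test[k] <- discriminability(test, w)$average_A
  }
  ok <- a_train > 0
  if (!any(ok))
    stop("training discriminability was zero in every split", call. = FALSE)
  list(ratio = mean(a_test[ok] / a_train[ok]),
       a_train = a_train, a_test = a_test, degenerate = !all(ok))
}
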