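test_that("drop_unit zeroes one weight and respects symmetry", {
  w <- weight_vector(c(0.5, 0.5, 0.5, 0.5))
  wd <- drop_unit(w, 3)
  expect_identical(wd$weights[3], 0)
  expect_equal(sqrt(sum(wd$weights^2)), 1)
  # dropping an already-zero unit changes nothing (hence A unchanged)
  w0 <- weight_vector(c(1, 0, 1))
  expect_equal(drop_unit(w0, 2)$weights, w0$weights)
  expect_error(drop_unit(weight_vector(1), 1), "single-neuron")
  # exchangeable 2-neuron population: either drop gives identical A
  tp <- tuning_params(baseline = c(2, 2), gain = c(5, 5),
                      midpoint = c(12, 12), slope = c(4, 4))
  rec <- generate_population(tp, noise_model(fano_factor = 1, rho = 0.2),
                             n_trials = 200, seed = 1)
  wopt <- weight_vector(c(1, 1))
  a1 <- discriminability(rec, drop_unit(wopt, 1))$average_A
  a2 <- discriminability(rec, drop_unit(wopt, 2))$average_A
  # both reduce to single-neuron readouts of identically-tuned neurons
  expect_equal(a1, discriminability(rec, c(0, 1))$average_A)
  expect_equal(a2, discriminability(rec, c(1, 0))$average_A)
})

test_that("dropping units can only help so much: suboptimal <= optimal on training data", {
  for (seed in c(5, 6)) {
    rec <- make_pop(n = 5, seed = seed, n_trials = 50)
    w <- fit_decoder(rec, "groupwise_optimal")
    a_full <- discriminability(rec, w)$average_A
    drops <- sapply(1:5, function(i)
      discriminability(rec, drop_unit(w, i))$average_A)
    expect_lte(mean(drops), a_full + 1e-12)
  }
})

test_that("orthogonalized eigenbasis is orthonormal, spans the space, starts at optimal", {
  rec <- make_pop(n = 6, seed = 8, n_trials = 50)
  d <- cov_decompose(rec)
  basis <- orthogonalized_eigenbasis(d)
  g <- crossprod(basis)
  expect_lt(max(abs(g - diag(6))), 1e-10)
  # projector onto the basis equals the identity
  expect_lt(max(abs(basis %*% t(basis) - diag(6))), 1e-8)
  w <- groupwise_optimal(d)
  expect_equal(basis[, 1], w$weights, tolerance = 1e-8)
  # diagonal case: eigenvectors already orthogonal, basis equals them
  dd <- list(signal_cov = diag(c(5, 2, 1)), noise_cov = diag(3),
             active_mask = rep(TRUE, 3),
             per_stimulus_mean = cbind(c(0, 0, 0), c(1, 1, 1)))
  b3 <- orthogonalized_eigenbasis(dd)
  expect_equal(abs(b3), diag(3), tolerance = 1e-10)
  # N = 2: second vector is the unique orthogonal complement up to sign
  rec2 <- make_pop(n = 2, seed = 9, n_trials = 40)
  b2 <- orthogonalized_eigenbasis(cov_decompose(rec2))
  expect_equal(abs(sum(b2[, 1] * b2[, 2])), 0, tolerance = 1e-12)
})

test_that("rotation has exact angles and leaves the orthogonal complement fixed", {
  set.seed(4)
  v <- unit_norm_test(rnorm(5))
  d <- unit_norm_test(rnorm(5))
  expect_equal(rotate_weights(v, d, 0)$weights, v)
  for (th in seq(10, 170, by = 20)) {
    wr <- rotate_weights(v, d, th)$weights
    expect_equal(acos(sum(wr * v)) * 180 / pi, th, tolerance = 1e-8)
    # stays inside span{v, d}
    resid <- wr - (sum(wr * v) * v)
    dp <- d - sum(d * v) * v; dp <- dp / sqrt(sum(dp^2))
    resid <- resid - sum(resid * dp) * dp
    expect_lt(sqrt(sum(resid^2)), 1e-10)
  }
  # angle 90 with an orthonormal direction returns the direction
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(rotate_weights(e1, e2, 90)$weights, e2, tolerance = 1e-12)
  expect_error(rotate_weights(e1, -e1, 30), "parallel")
})

test_that("identity-line trajectory endpoints reproduce pooling exactly", {
  rec <- make_pop(n = 5, seed = 14, rho = 0.3, n_trials = 60)
  w <- fit_decoder(rec, "groupwise_optimal")
  tr <- rotation_toward_identity(rec, w)
  a_pool <- discriminability(rec, pooling_weights(5))$average_A
  ends <- tapply(seq_len(nrow(tr)), tr$path, function(i)
    tr$average_A[i[which.max(abs(tr$angle_deg[i]))]])
  expect_identical(as.numeric(ends["short"]), a_pool)
  expect_identical(as.numeric(ends["long"]), a_pool)
  expect_equal(tr$average_A[tr$angle_deg == 0][1],
               discriminability(rec, w)$average_A)
  expect_equal(tr$relative_A[tr$angle_deg == 0][1], 1)
  # full 180-degree circuit: the two path lengths sum to 180
  expect_equal(max(tr$angle_deg) - min(tr$angle_deg), 180, tolerance = 1e-8)
})

test_that("performance dips near 90 degrees from optimal on correlated data", {
  mins <- sapply(c(15, 16, 17), function(seed) {
    rec <- make_pop(n = 6, seed = seed, rho = 0.35, n_trials = 60)
    tr <- rotation_toward_identity(rec, fit_decoder(rec, "groupwise_optimal"),
                                   step_deg = 10)
    abs(tr$angle_deg[which.min(tr$average_A)])
  })
  expect_true(mean(mins >= 50 & mins <= 130) >= 2 / 3)
})

test_that("rotation costs less along higher-eigenvalue dimensions", {
  # populations with two tuning subgroups, so the second eigen-dimension
  # carries real signal and the spectrum is well separated
  drops2 <- drops_last <- numeric(6)
  for (k in 1:6) {
    rec <- make_two_group_pop(seed = 330 + k)
    tab <- rotation_toward_dimensions(rec, angles_deg = c(0, 30, 90))
    r30 <- tab[tab$angle_deg == 30, ]
    drops2[k] <- 1 - r30$relative_A[r30$dimension == 2]
    drops_last[k] <- 1 - r30$relative_A[r30$dimension == 6]
    # fully rotated (90 degrees): A is ordered by the eigenvalue rank
    r90 <- tab[tab$angle_deg == 90, ]
    expect_gt(r90$average_A[r90$dimension == 2],
              r90$average_A[r90$dimension == 6])
  }
  expect_lt(mean(drops2), mean(drops_last))
})

test_that("angular difference matches analytic cases and split-half bias is small without noise", {
  expect_equal(angular_difference(c(1, 0), c(1, 0)), 0)
  expect_equal(angular_difference(c(1, 0), c(sqrt(2) / 2, sqrt(2) / 2)), 45,
               tolerance = 1e-10)
  expect_error(angular_difference(c(0, 0), c(1, 0)), "zero")
  # near-deterministic population: halves agree, bias ~ 0
  tp <- tuning_params(baseline = c(0, 0, 0), gain = c(20, 12, 30),
                      midpoint = c(8, 14, 20), slope = c(2, 3, 2))
  rec <- generate_population(tp, noise_model(fano_factor = 1, rho = 0),
                             n_trials = 400, seed = 31)
  b <- split_half_bias(rec, n_splits = 10, seed = 32)
  expect_lt(b, 15)
  # noisier data give a larger bias than near-deterministic data
  rec_noisy <- make_pop(n = 3, seed = 33, n_trials = 40)
  expect_gt(split_half_bias(rec_noisy, n_splits = 10, seed = 34), b / 2)
})

test_that("split-half generalization is near 1 for matched-structure populations", {
  rec <- make_pop(n = 8, seed = 41, rho = 0.2, n_trials = 100)
  g <- split_half_generalization(rec, n_splits = 10, seed = 42)
  expect_gt(g$ratio, 0.9)
  expect_false(g$degenerate)
  # deterministic given the seed
  g2 <- split_half_generalization(rec, n_splits = 1, seed = 43)
  g3 <- split_half_generalization(rec, n_splits = 1, seed = 43)
  expect_identical(g2$ratio, g3$ratio)
  expect_error(split_half_generalization(
    subset_trials(rec, 1:99), n_splits = 2, seed = 1), "even")
})
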