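test_that("covariance decomposition matches a brute-force oracle", {
  # 2 neurons, 3 stimuli, 3 trials, hand-enumerable
  counts <- array(0L, dim = c(2, 3, 3))
  counts[1, , ] <- matrix(c(0, 1, 2, 2, 3, 4, 4, 6, 8), 3, 3, byrow = TRUE)
  counts[2, , ] <- matrix(c(1, 1, 1, 0, 2, 4, 3, 3, 6), 3, 3, byrow = TRUE)
  rec <- rec_from_counts(counts)
  d <- cov_decompose(rec)
  # elementwise covariance oracle with divisor T-1
  cov_oracle <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  for (s in 1:3) {
    for (i in 1:2) for (j in 1:2) {
      expect_equal(d$per_stimulus_cov[i, j, s],
                   cov_oracle(counts[i, s, ], counts[j, s, ]))
    }
  }
  expect_equal(d$noise_cov, apply(d$per_stimulus_cov, c(1, 2), mean))
  mu <- apply(counts, c(1, 2), mean)
  expect_equal(d$per_stimulus_mean, mu)
  for (i in 1:2) for (j in 1:2)
    expect_equal(d$signal_cov[i, j], cov_oracle(mu[i, ], mu[j, ]))
  expect_equal(d$grand_mean, rowMeans(mu))
  expect_error(cov_decompose(rec_from_counts(counts[, , 1, drop = FALSE])),
               "two trials")
})

test_that("silent neurons are masked out and given weight zero", {
  rec <- make_pop(n = 3, seed = 5, n_trials = 20)
  counts <- rec$counts
  counts[2, , ] <- 0L
  rec0 <- rec_from_counts(counts, rec$amplitudes)
  d <- cov_decompose(rec0)
  expect_equal(d$active_mask, c(TRUE, FALSE, TRUE))
  expect_identical(groupwise_optimal(d)$weights[2], 0)
  expect_identical(pairwise_optimal(d, 1, 12)$weights[2], 0)
  # all trials identical at every stimulus -> zero noise covariance
  cc <- array(3L, dim = c(2, 3, 4)); cc[1, , ] <- c(1L, 2L, 3L)
  expect_equal(cov_decompose(rec_from_counts(cc))$noise_cov,
               matrix(0, 2, 2))
})

test_that("groupwise weights solve the generalized eigenproblem", {
  rec <- make_pop(n = 5, seed = 9, n_trials = 50)
  d <- cov_decompose(rec)
  w <- groupwise_optimal(d)
  lam <- attr(w, "snr")
  resid <- d$signal_cov %*% w$weights - lam * (d$noise_cov %*% w$weights)
  rel <- sqrt(sum(resid^2)) / sqrt(sum((d$signal_cov %*% w$weights)^2))
  expect_lt(rel, 1e-8)
  expect_equal(sqrt(sum(w$weights^2)), 1)
  expect_equal(snr_of(d, w), lam, tolerance = 1e-10)
  # sign canonicalization: strongest stimulus projects above weakest
  expect_gt(sum(w$weights * (d$per_stimulus_mean[, 12] -
                             d$per_stimulus_mean[, 1])), 0)
})

test_that("groupwise SNR beats random and grid search within 1%", {
  for (seed in c(21, 22)) {
    rec <- make_pop(n = 3, seed = seed, n_trials = 40)
    d <- cov_decompose(rec)
    w <- groupwise_optimal(d)
    snr_w <- snr_of(d, w)
    set.seed(seed)
    vs <- matrix(rnorm(3 * 20000), 3)
    snrs <- apply(vs, 2, function(v) snr_of(d, v))
    expect_gte(snr_w, max(snrs) - 1e-9)
    expect_gte(max(snrs), 0.99 * snr_w)  # the search does approach it
  }
  # exchangeable-neuron symmetry: optimal along the identity line
  tp <- tuning_params(baseline = c(2, 2), gain = c(5, 5),
                      midpoint = c(12, 12), slope = c(4, 4))
  rec <- generate_population(tp, noise_model(fano_factor = 1, rho = 0),
                             n_trials = 4000, seed = 30)
  w <- groupwise_optimal(cov_decompose(rec))
  expect_equal(w$weights, c(1, 1) / sqrt(2), tolerance = 0.08)
  # N = 1
  rec1 <- make_pop(n = 1, seed = 2, n_trials = 20)
  expect_equal(groupwise_optimal(cov_decompose(rec1))$weights, 1)
})

test_that("degenerate signal covariance yields flagged uniform weights", {
  cc <- array(0L, dim = c(2, 3, 6))
  cc[1, , ] <- rep(c(1L, 3L, 1L, 3L, 1L, 3L), each = 3)  # same at all stimuli
  cc[2, , ] <- rep(c(2L, 0L, 2L, 0L, 2L, 0L), each = 3)
  rec <- rec_from_counts(cc)
  expect_warning(w <- groupwise_optimal(cov_decompose(rec)), "no tuning")
  expect_true(w$degenerate)
})

test_that("pairwise-optimal matches the closed form and a 2-d grid search", {
  rec <- make_pop(n = 4, seed = 33, n_trials = 50)
  d <- cov_decompose(rec)
  w <- pairwise_optimal(d, 2, 9)
  pooled <- (d$per_stimulus_cov[, , 2] + d$per_stimulus_cov[, , 9]) / 2
  dmu <- d$per_stimulus_mean[, 2] - d$per_stimulus_mean[, 9]
  ref <- solve(pooled, dmu)
  ref <- ref / sqrt(sum(ref^2))
  if (sum(ref * w$weights) < 0) ref <- -ref
  expect_equal(w$weights, ref, tolerance = 1e-8)
  # grid-search oracle on the 2-neuron closed-form example:
  # pooled covariance diag(2, 1), dmu = (1, 1) -> w proportional to (0.5, 1)
  pair_snr <- function(v, pooled, dmu)
    (sum(v * dmu))^2 / sum(v * (pooled %*% v))
  pooled2 <- diag(c(2, 1)); dmu2 <- c(1, 1)
  angles <- seq(0, pi, length.out = 3600)
  snrs <- sapply(angles, function(t) pair_snr(c(cos(t), sin(t)), pooled2, dmu2))
  best <- c(cos(angles[which.max(snrs)]), sin(angles[which.max(snrs)]))
  expect_equal(abs(best / best[2]), c(0.5, 1), tolerance = 1e-3)
  expect_equal(pair_snr(c(0.5, 1), pooled2, dmu2), max(snrs),
               tolerance = 1e-6)
  # degenerate pair: identical means
  cc <- array(2L, dim = c(2, 3, 5))
  cc[, 3, ] <- 7L
  cc[1, 1, ] <- c(1L, 3L, 2L, 1L, 3L); cc[2, 1, ] <- c(3L, 1L, 2L, 3L, 1L)
  cc[1, 2, ] <- c(1L, 3L, 2L, 1L, 3L); cc[2, 2, ] <- c(3L, 1L, 2L, 3L, 1L)
  expect_warning(wd <- pairwise_optimal(cov_decompose(rec_from_counts(cc)), 1, 2),
                 "identical mean")
  expect_true(wd$degenerate)
})

test_that("pooling and best-neuron references behave as defined", {
  expect_equal(pooling_weights(4)$weights, rep(0.5, 4))
  expect_equal(pooling_weights(1)$weights, 1)
  # neuron 2 has strictly larger tuning range, equal noise -> best neuron
  tp <- tuning_params(baseline = c(2, 2, 2), gain = c(1, 8, 1),
                      midpoint = 12, slope = 4)
  rec <- generate_population(tp, noise_model(fano_factor = 1, rho = 0),
                             n_trials = 300, seed = 44)
  wb <- best_neuron_weights(rec)
  expect_equal(wb$weights, c(0, 1, 0))
  rec1 <- make_pop(n = 1, seed = 3, n_trials = 20)
  expect_equal(best_neuron_weights(rec1)$weights, 1)
})

test_that("diagonal decoder ignores off-diagonal noise covariance", {
  # already-diagonal noise: identical to the groupwise solution
  rec <- make_pop(n = 4, seed = 51, rho = 0, n_trials = 2000)
  d <- cov_decompose(rec)
  wg <- groupwise_optimal(d); wd <- diagonal_decoder(d)
  expect_equal(wd$weights, wg$weights, tolerance = 0.05)
  # strongly correlated noise: diagonal can't beat the full solution in SNR
  rec2 <- make_pop(n = 5, seed = 52, rho = 0.5, n_trials = 100)
  d2 <- cov_decompose(rec2)
  expect_lte(snr_of(d2, diagonal_decoder(d2)),
             snr_of(d2, groupwise_optimal(d2)) + 1e-12)
  # and (empirically, on training data) in average A
  expect_lte(discriminability(rec2, diagonal_decoder(d2))$average_A,
             discriminability(rec2, groupwise_optimal(d2))$average_A + 0.005)
})

test_that("a_optimum pattern search improves A and respects its budget", {
  rec <- make_pop(n = 3, seed = 61, n_trials = 30,
                  amplitudes = seq(0, 33, by = 11))  # S = 4: fast objective
  init <- fit_decoder(rec, "groupwise_optimal")
  w <- a_optimum(rec, init, budget = 400)
  expect_gte(attr(w, "average_A"),
             discriminability(rec, init)$average_A - 1e-12)
  # budget 0 returns init unchanged with a status flag
  w0 <- a_optimum(rec, init, budget = 0)
  expect_equal(w0$weights, init$weights)
  expect_identical(attr(w0, "status"), "budget_exhausted")
  # deterministic given init and budget
  w2 <- a_optimum(rec, init, budget = 400)
  expect_identical(w$weights, w2$weights)
})

test_that("a_optimum approaches an exhaustive rotation sweep in 2-D", {
  rec <- make_pop(n = 2, seed = 62, n_trials = 40,
                  amplitudes = seq(0, 33, by = 11))
  init <- fit_decoder(rec, "groupwise_optimal")
  w <- a_optimum(rec, init, budget = 600)
  angles <- seq(0, pi, length.out = 181)  # 1 degree sweep
  sweep_best <- max(sapply(angles, function(t)
    discriminability(rec, c(cos(t), sin(t)))$average_A))
  expect_gte(attr(w, "average_A"), sweep_best * 0.99)
})

test_that("scheme ordering holds on training data", {
  for (seed in c(71, 72, 73)) {
    rec <- make_pop(n = 5, seed = seed, rho = 0.25, n_trials = 50)
    a <- sapply(c("pooling", "best_neuron", "groupwise_optimal"),
                function(s) discriminability(rec, fit_decoder(rec, s))$average_A)
    expect_gte(a["groupwise_optimal"], a["pooling"] - 0.01)
    expect_gte(a["groupwise_optimal"], a["best_neuron"] - 0.01)
  }
})

test_that("weight magnitude tracks single-neuron SNR", {
  rhos <- sapply(c(81, 82, 83, 84), function(seed) {
    rec <- make_pop(n = 8, seed = seed, rho = 0.1, n_trials = 60)
    d <- cov_decompose(rec)
    w <- abs(groupwise_optimal(d)$weights)
    snr1 <- diag(d$signal_cov) / diag(d$noise_cov)
    cor(w, snr1, method = "spearman")
  })
  expect_gt(mean(rhos), 0)
  expect_gt(sum(rhos > 0), 2)
})
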