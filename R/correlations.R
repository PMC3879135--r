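#' Signal correlation index (SCI)
#'
#' Quantifies the similarity of tuning curves across the population by the
#' leading eigenvalue of the tuning-curve correlation matrix. Each neuron's
#' mean responses across the S stimuli are z-scored; the N x N correlation
#' matrix of these tuning curves has eigenvalues summing to N, and the
#' leading eigenvalue normalized by N (`lambda1_bar`) measures the maximal
#' shared covariation. Because `lambda1_bar` has a floor of
#' `b = 1/min(N, S-1)` (the rank of the matrix is at most `min(N, S-1)`),
#' the index is bias-corrected and rescaled to `[0, 1]`:
#' `SCI = (lambda1_bar - b) / (1 - b)`, clipped at 0 and 1. For N = 2 the
#' SCI equals the absolute Pearson correlation between the two tuning
#' curves exactly.
#'
#' Neurons with constant tuning (zero variance of the mean response across
#' stimuli) have no defined z-score and are excluded with a warning; `N` in
#' the bias term is the retained count.
#'
#' @param recording A [population_recording] with at least 2 neurons and 2
#'   stimuli.
#' @return A list of class `correlation_index`: `index` (the SCI),
#'   `eigenvalues` (descending, of the retained-neuron correlation matrix),
#'   `bias`, `n_retained`, `kind = "signal"`.
#' @export
signal_correlation_index <- function(recording) {
  if (n_neurons(recording) < 2 || n_stimuli(recording) < 2)
    stop("need at least two neurons and two stimuli", call. = FALSE)
  m <- stimulus_means(recording)
  keep <- apply(m, 1L, stats::sd) > 0
  if (!all(keep))
    warning(sprintf(
      "%d neuron(s) with constant tuning excluded from the SCI", sum(!keep)))
  if (sum(keep) < 2)
    stop("fewer than two neurons with non-constant tuning", call. = FALSE)
  r <- stats::cor(t(m[keep, , drop = FALSE]))
  index_from_corr(r, s_eff = n_stimuli(recording), kind = "signal")
}

#' Noise correlation index (NCI)
#'
#' The analogue of [signal_correlation_index] for trial-to-trial
#' variability: per-stimulus trial correlation matrices are averaged across
#' stimuli, and the leading eigenvalue of the average matrix, normalized by
#' N and bias-corrected with `b = 1/min(N, T-1)`, is rescaled to `[0, 1]`.
#' For N = 2 the NCI equals the absolute average trial-by-trial correlation
#' coefficient. A neuron with zero variance at some stimulus contributes
#' zero correlations at that stimulus (its diagonal stays 1); neurons with
#' zero variance at every stimulus are dropped with a warning.
#'
#' @param recording A [population_recording] with at least 2 neurons and 3
#'   trials.
#' @return A list of class `correlation_index` as in
#'   [signal_correlation_index], with `kind = "noise"`.
#' @export
noise_correlation_index <- function(recording) {
  if (n_neurons(recording) < 2)
    stop("need at least two neurons", call. = FALSE)
  if (n_trials(recording) < 3)
    stop("need at least three trials", call. = FALSE)
  s <- n_stimuli(recording)
  sds <- apply(recording$counts, c(1L, 2L), stats::sd)
  keep <- rowSums(sds > 0) > 0
  if (!all(keep))
    warning(sprintf(
      "%d neuron(s) with zero variance at every stimulus dropped from the NCI",
      sum(!keep)))
  if (sum(keep) < 2)
    stop("fewer than two neurons with trial-to-trial variability",
         call. = FALSE)
  counts <- recording$counts[keep, , , drop = FALSE]
  n <- sum(keep)
  acc <- matrix(0, n, n)
  for (k in seq_len(s)) {
    x <- t(counts[, k, ])
    ok <- apply(x, 2L, stats::sd) > 0
    r <- diag(1, n)
    if (sum(ok) >= 2)
      r[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
    acc <- acc + r
  }
  index_from_corr(acc / s, s_eff = n_trials(recording), kind = "noise")
}

# Shared eigenvalue -> bias-corrected index step. s_eff is the number of
# observations behind the correlation matrix (S stimuli or T trials).
index_from_corr <- function(r, s_eff, kind) {
  n <- nrow(r)
  ev <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(sort(ev, decreasing = TRUE), 0)
  b <- 1 / min(n, s_eff - 1)
  idx <- clamp((ev[1] / n - b) / (1 - b), 0, 1)
  structure(list(index = idx, eigenvalues = ev, bias = b,
                 n_retained = n, kind = kind),
            class = "correlation_index")
}

#' @export
print.correlation_index <- function(x, ...) {
  cat(sprintf("<correlation_index> %s: %.4f (N = %d, bias = %.4f)\n",
              toupper(substr(x$kind, 1, 1)), x$index, x$n_retained, x$bias))
  invisible(x)
}

#' Trial shuffling: destroy noise correlation, keep marginals
#'
#' Independently permutes each neuron's trial order within every stimulus.
#' The per-neuron, per-stimulus count multisets -- and therefore the
#' per-stimulus means and the signal correlation -- are unchanged, while
#' trial-to-trial covariation across neurons is destroyed.
#'
#' @param recording A [population_recording].
#' @param seed Integer seed.
#' @return A [population_recording] with decorrelated trials.
#' @export
trial_shuffle <- function(recording, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  counts <- recording$counts
  n <- dim(counts)[1L]; s <- dim(counts)[2L]; t <- dim(counts)[3L]
  counts <- with_seed(seed, {
    for (k in seq_len(s)) for (i in seq_len(n))
      counts[i, k, ] <- counts[i, k, sample.int(t)]
    counts
  })
  population_recording(counts, recording$amplitudes, state = recording$state,
                       unit_kind = recording$unit_kind,
                       neuron_ids = recording$neuron_ids)
}

#' Stimulus shuffling: destroy tuning alignment
#'
#' Independently permutes each neuron's stimulus labels (whole per-stimulus
#' trial blocks move together), destroying the alignment of tuning curves
#' across neurons while leaving each neuron's own response statistics
#' intact. Used as a control showing that the SCI reflects cross-neuron
#' signal correlation rather than single-neuron response structure.
#'
#' @inheritParams trial_shuffle
#' @return A [population_recording] with per-neuron permuted stimulus
#'   labels.
#' @export
stimulus_shuffle <- function(recording, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  counts <- recording$counts
  n <- dim(counts)[1L]; s <- dim(counts)[2L]
  counts <- with_seed(seed, {
    for (i in seq_len(n))
      counts[i, , ] <- counts[i, sample.int(s), ]
    counts
  })
  population_recording(counts, recording$amplitudes, state = recording$state,
                       unit_kind = recording$unit_kind,
                       neuron_ids = recording$neuron_ids)
}

#' Effect of noise correlation on decoding performance
#'
#' `delta_a_shuffled` is the percent change in the average discriminability
#' `A` when the decoder is optimized and evaluated on trial-shuffled
#' (decorrelated) responses, relative to the decoder optimized and
#' evaluated on the true responses, averaged over `n_shuffles` independent
#' shuffles: `100 * (A_shuffled - A_true) / A_true`. A positive value means
#' noise correlation was hurting that decoding scheme.
#'
#' `delta_a_diag` is the percent change in `A`, on the true responses, of
#' the correlation-blind [diagonal_decoder] relative to the full
#' [groupwise_optimal] decoder: `100 * (A_diag - A_opt) / A_opt`. Negative
#' values are the cost of ignoring noise correlation.
#'
#' @param recording A [population_recording].
#' @param scheme Decoding scheme name (see [fit_decoder]).
#' @param n_shuffles Number of trial shuffles to average (>= 1; 50 in the
#'   canonical design).
#' @param seed Integer seed.
#' @return A single percentage.
#' @export
delta_a_shuffled <- function(recording, scheme = "groupwise_optimal",
                             n_shuffles = 50, seed) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  a_true <- scheme_average_a(recording, scheme)
  if (a_true == 0)
    stop("average A on the true responses is zero; the percent change is ",
         "undefined", call. = FALSE)
  seeds <- child_seeds(seed, n_shuffles)
  a_shuf <- vapply(seeds, function(s)
    scheme_average_a(trial_shuffle(recording, s), scheme), numeric(1))
  100 * mean(a_shuf - a_true) / a_true
}

#' @rdname delta_a_shuffled
#' @export
delta_a_diag <- function(recording) {
  d <- cov_decompose(recording)
  a_opt <- average_a(recording, groupwise_optimal(d))
  if (a_opt == 0)
    stop("optimal average A is zero; the percent change is undefined",
         call. = FALSE)
  a_diag <- average_a(recording, diagonal_decoder(d))
  100 * (a_diag - a_opt) / a_opt
}

# Fit `scheme` on a recording and evaluate its average A on the same
# recording (training performance).
scheme_average_a <- function(recording, scheme, ...) {
  w <- fit_decoder(recording, scheme, ...)
  discriminability(recording, w)$average_A
}

#' Angle between the leading signal and noise directions
#'
#' The angle, in degrees within `[0, 90]`, between the first eigenvectors
#' of the signal and noise covariance matrices:
#' `acos(|u1 . v1|)`. A warning flags near-degenerate leading eigenspaces
#' (relative gap below `1e-8`), where the direction is not well defined.
#'
#' @param decomp A [cov_decompose] result.
#' @return Angle in degrees.
#' @export
signal_noise_angle <- function(decomp) {
  eg_s <- eigen((decomp$signal_cov + t(decomp$signal_cov)) / 2,
                symmetric = TRUE)
  eg_n <- eigen((decomp$noise_cov + t(decomp$noise_cov)) / 2,
                symmetric = TRUE)
  for (eg in list(eg_s, eg_n)) {
    if (length(eg$values) > 1 &&
        (eg$values[1] - eg$values[2]) <= 1e-8 * max(abs(eg$values[1]), 1e-300))
      warning("leading eigenvalue is (near-)degenerate; the signal/noise ",
              "direction is not unique")
  }
  d <- abs(sum(eg_s$vectors[, 1] * eg_n$vectors[, 1]))
  rad2deg(acos(clamp(d, 0, 1)))
}
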