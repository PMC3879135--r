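#' Signal/noise covariance decomposition of a recording
#'
#' The substrate of the Fisher-discriminant analyses. Per-stimulus trial
#' covariances use the unbiased divisor `T - 1`; the noise covariance is
#' their unweighted mean across stimuli (equal trial counts per stimulus);
#' the signal covariance is the sample covariance of the per-stimulus mean
#' response vectors about the grand mean (divisor `S - 1`). Neurons whose
#' average spike count over all stimuli and trials is zero are flagged
#' inactive; every optimal-weight solver restricts itself to active neurons
#' and assigns the rest weight zero, which is how the singular-covariance
#' case is resolved.
#'
#' @param recording A [population_recording] with `T >= 2` and `S >= 2`.
#' @return A list of class `cov_decomp` with elements `per_stimulus_mean`
#'   (N x S), `grand_mean` (N), `signal_cov` (N x N), `noise_cov` (N x N),
#'   `per_stimulus_cov` (N x N x S array), `active_mask` (logical N), and
#'   `amplitudes`.
#' @export
cov_decompose <- function(recording) {
  if (n_trials(recording) < 2)
    stop("need at least two trials per stimulus", call. = FALSE)
  if (n_stimuli(recording) < 2)
    stop("need at least two stimuli", call. = FALSE)
  n <- n_neurons(recording); s <- n_stimuli(recording)
  mu <- stimulus_means(recording)
  per_cov <- array(0, dim = c(n, n, s))
  for (k in seq_len(s))
    per_cov[, , k] <- stats::cov(t(matrix(recording$counts[, k, ], nrow = n)))
  noise_cov <- apply(per_cov, c(1, 2), mean)
  signal_cov <- stats::cov(t(mu))
  structure(
    list(per_stimulus_mean = mu,
         grand_mean = rowMeans(mu),
         signal_cov = signal_cov,
         noise_cov = noise_cov,
         per_stimulus_cov = per_cov,
         active_mask = rowMeans(mu) > 0,
         amplitudes = recording$amplitudes,
         state = recording$state),
    class = "cov_decomp")
}

#' @export
print.cov_decomp <- function(x, ...) {
  cat(sprintf("<cov_decomp> %d neurons (%d active), %d stimuli\n",
              nrow(x$signal_cov), sum(x$active_mask),
              ncol(x$per_stimulus_mean)))
  invisible(x)
}

# Canonical sign: the projection of the highest-amplitude stimulus mean
# must exceed that of the lowest. A is unaffected; output is reproducible.
canonical_sign <- function(w, mu) {
  s <- ncol(mu)
  if (sum(w * (mu[, s] - mu[, 1])) < 0) -w else w
}

#' Groupwise-optimal (Fisher) decoding weights
#'
#' Maximizes the average signal-to-noise ratio
#' `SNR(w) = (w' Sigma_signal w) / (w' Sigma_noise w)` over the whole
#' stimulus set. The maximizer is the top generalized eigenvector of
#' `(Sigma_signal, Sigma_noise)`, computed in symmetric (noise-whitened)
#' form for numerical stability: with `W = Sigma_noise^{-1/2}`, the top
#' eigenvector `v` of `W Sigma_signal W` gives `w = W v`. Inactive neurons
#' (zero average count) receive weight exactly zero; a ridge of
#' `1e-8 * trace/N` is added only if the active-neuron noise covariance is
#' still singular.
#'
#' @param decomp A [cov_decompose] result.
#' @return A unit-norm [weight_vector] with `scheme = "groupwise_optimal"`
#'   and attribute `snr` (the attained ratio). If the signal covariance is
#'   zero (no tuning), returns uniform weights over active neurons flagged
#'   `degenerate`, with a warning.
#' @export
groupwise_optimal <- function(decomp) {
  fisher_weights(decomp, diagonal = FALSE)
}

#' Diagonal (correlation-blind) decoding weights
#'
#' The groupwise solution computed after setting the off-diagonal elements
#' of the noise covariance to zero: the decoder is optimized as if neurons
#' were uncorrelated, then applied to the true responses. Comparing its
#' performance with [groupwise_optimal] measures the cost of ignoring noise
#' correlation.
#'
#' @inheritParams groupwise_optimal
#' @return A unit-norm [weight_vector] with `scheme = "diagonal"`.
#' @export
diagonal_decoder <- function(decomp) {
  fisher_weights(decomp, diagonal = TRUE)
}

fisher_weights <- function(decomp, diagonal = FALSE) {
  act <- decomp$active_mask
  n <- length(act)
  scheme <- if (diagonal) "diagonal" else "groupwise_optimal"
  if (!any(act)) {
    warning("no active neurons; returning uniform degenerate weights")
    return(weight_vector(rep(1, n), scheme, trained_state = decomp$state,
                         degenerate = TRUE))
  }
  sig <- decomp$signal_cov[act, act, drop = FALSE]
  noi <- decomp$noise_cov[act, act, drop = FALSE]
  if (diagonal) noi <- diag(diag(noi), nrow = nrow(noi))
  if (max(abs(sig)) == 0) {
    warning("signal covariance is zero (no tuning); ",
            "returning uniform degenerate weights")
    w <- rep(0, n); w[act] <- 1
    return(weight_vector(w, scheme, trained_state = decomp$state,
                         degenerate = TRUE))
  }
  if (sum(act) == 1) {
    w <- rep(0, n); w[act] <- 1
    out <- weight_vector(w, scheme, trained_state = decomp$state)
    attr(out, "snr") <- sig[1, 1] / noi[1, 1]
    return(out)
  }
  wm <- inv_sqrt_sym(noi)
  m <- wm %*% sig %*% wm
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  wa <- as.numeric(wm %*% eg$vectors[, 1])
  w <- rep(0, n); w[act] <- wa
  w <- canonical_sign(unit_norm(w), decomp$per_stimulus_mean)
  out <- weight_vector(w, scheme, trained_state = decomp$state)
  attr(out, "snr") <- eg$values[1]
  out
}

#' Attained signal-to-noise ratio of a weight vector
#'
#' @param decomp A [cov_decompose] result.
#' @param w A [weight_vector] or numeric vector.
#' @return `(w' Sigma_signal w) / (w' Sigma_noise w)`.
#' @export
snr_of <- function(decomp, w) {
  v <- as_weights(w, nrow(decomp$signal_cov))
  num <- sum(v * (decomp$signal_cov %*% v))
  den <- sum(v * (decomp$noise_cov %*% v))
  if (den <= 0) stop("weight vector has zero noise variance", call. = FALSE)
  num / den
}

#' Pairwise-optimal (two-class Fisher) decoding weights
#'
#' For one stimulus pair the signal-to-noise ratio reduces to the two-class
#' Fisher criterion, whose maximizer has the closed form
#' `w = Sigma_pooled^{-1} (mu_i - mu_j)` with `Sigma_pooled` the mean of
#' the two per-stimulus covariances -- identical to least-squares
#' estimation of the two classes. Restricted to active neurons; zeros
#' elsewhere.
#'
#' @param decomp A [cov_decompose] result.
#' @param i,j Distinct stimulus indices.
#' @return A unit-norm [weight_vector] with `scheme = "pairwise_optimal"`.
#'   If `mu_i == mu_j` the result is flagged `degenerate` (zero signal).
#' @export
pairwise_optimal <- function(decomp, i, j) {
  s <- ncol(decomp$per_stimulus_mean)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || i < 1 || j < 1 || i > s || j > s)
    stop("need two distinct stimulus indices in 1..S", call. = FALSE)
  act <- decomp$active_mask
  n <- length(act)
  dmu <- decomp$per_stimulus_mean[act, i] - decomp$per_stimulus_mean[act, j]
  if (all(dmu == 0)) {
    warning("identical mean responses for the stimulus pair; degenerate")
    w <- rep(0, n); w[act] <- 1
    return(weight_vector(w, "pairwise_optimal", trained_state = decomp$state,
                         degenerate = TRUE))
  }
  pooled <- (decomp$per_stimulus_cov[act, act, i, drop = FALSE][, , 1] +
             decomp$per_stimulus_cov[act, act, j, drop = FALSE][, , 1]) / 2
  pooled <- matrix(pooled, sum(act), sum(act))
  eg <- eigen((pooled + t(pooled)) / 2, symmetric = TRUE, only.values = TRUE)
  if (min(eg$values) <= max(eg$values) * 1e-10) {
    eps <- 1e-8 * sum(diag(pooled)) / nrow(pooled)
    pooled <- pooled + diag(max(eps, 1e-12), nrow(pooled))
  }
  wa <- solve(pooled, dmu)
  w <- rep(0, n); w[act] <- wa
  # canonical sign within the pair: higher-amplitude mean projects higher
  hi <- max(i, j); lo <- min(i, j)
  if (sum(w * (decomp$per_stimulus_mean[, hi] -
               decomp$per_stimulus_mean[, lo])) < 0) w <- -w
  weight_vector(w, "pairwise_optimal", trained_state = decomp$state)
}

# All S(S-1)/2 pairwise-optimal weights in upper-triangle order.
pairwise_optimal_all <- function(decomp) {
  s <- ncol(decomp$per_stimulus_mean)
  out <- vector("list", s * (s - 1) / 2)
  idx <- 0L
  for (j in 2:s) for (i in 1:(j - 1)) {
    idx <- idx + 1L
    out[[idx]] <- pairwise_optimal(decomp, i, j)
  }
  out
}

#' Reference decoding schemes: pooling and best neuron
#'
#' Pooling applies equal weights to all neurons (the identity-line
#' direction), i.e. it sums the population response. The best-neuron scheme
#' (lower envelope principle) gives weight 1 to the single neuron with the
#' highest average single-neuron discriminability `A` over all stimulus
#' pairs, and 0 to all others.
#'
#' @param n_neurons Population size (pooling).
#' @param recording A [population_recording] (best neuron).
#' @return A unit-norm [weight_vector].
#' @export
pooling_weights <- function(n_neurons) {
  stopifnot(n_neurons >= 1)
  weight_vector(rep(1, n_neurons), "pooling")
}

#' @rdname pooling_weights
#' @export
best_neuron_weights <- function(recording) {
  n <- n_neurons(recording)
  a <- vapply(seq_len(n), function(i) {
    e <- rep(0, n); e[i] <- 1
    average_a(recording, e)
  }, numeric(1))
  best <- which(a == max(a))
  if (length(best) > 1)
    message("tie for best neuron; choosing the lowest index")
  e <- rep(0, n); e[best[1]] <- 1
  weight_vector(e, "best_neuron", trained_state = recording$state)
}

#' Direct numerical maximization of the average discriminability
#'
#' Refines a starting weight vector by derivative-free coordinate pattern
#' search (Hooke-Jeeves style exploratory moves) on the average ROC area
#' `A` itself, rather than the SNR surrogate. Each coordinate is probed at
#' `+step` and `-step`; the step halves when no move improves, and the
#' search stops below a step tolerance of `1e-3` or when the evaluation
#' budget is exhausted. Deterministic given `init` and `budget`.
#'
#' @param recording A [population_recording] (the training trials).
#' @param init Starting [weight_vector]; conventionally the
#'   [groupwise_optimal] solution.
#' @param budget Maximum number of average-A evaluations (>= 0).
#' @param step Initial per-coordinate step size.
#' @return A unit-norm [weight_vector] with `scheme = "a_optimum"` and
#'   attributes `average_A` (attained value), `evaluations`, and `status`
#'   (`"converged"` or `"budget_exhausted"`).
#' @export
a_optimum <- function(recording, init, budget = 500, step = 0.1) {
  v <- as_weights(init, n_neurons(recording))
  if (budget < 0) stop("budget must be >= 0", call. = FALSE)
  best <- average_a(recording, v)
  evals <- 0L
  status <- "converged"
  n <- length(v)
  while (step >= 1e-3) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (delta in c(step, -step)) {
        if (evals >= budget) break
        cand <- v; cand[i] <- cand[i] + delta
        if (all(cand == 0)) next
        a <- average_a(recording, unit_norm(cand))
        evals <- evals + 1L
        if (a > best + 1e-12) {
          best <- a; v <- cand; improved <- TRUE
          break
        }
      }
      if (evals >= budget) break
    }
    if (evals >= budget && !improved) { status <- "budget_exhausted"; break }
    if (!improved) step <- step / 2
  }
  # sign left as inherited from `init`: A is sign-invariant and a zero-move
  # search must return the start vector unchanged
  out <- weight_vector(unit_norm(v), "a_optimum",
                       trained_state = recording$state)
  attr(out, "average_A") <- best
  attr(out, "evaluations") <- evals
  attr(out, "status") <- status
  out
}

#' Fit a decoding scheme by name
#'
#' Dispatcher used by the pipeline and perturbation analyses. For
#' `"pairwise_optimal"` a list of per-pair weight vectors is returned; all
#' other schemes return a single [weight_vector].
#'
#' @param recording A [population_recording].
#' @param scheme Scheme name (see [weight_vector]).
#' @param ... Passed to [a_optimum] (e.g. `budget`).
#' @return A [weight_vector], or a list of them for `"pairwise_optimal"`.
#' @export
fit_decoder <- function(recording, scheme, ...) {
  switch(scheme,
    pooling = pooling_weights(n_neurons(recording)),
    best_neuron = best_neuron_weights(recording),
    groupwise_optimal = groupwise_optimal(cov_decompose(recording)),
    diagonal = diagonal_decoder(cov_decompose(recording)),
    pairwise_optimal = pairwise_optimal_all(cov_decompose(recording)),
    a_optimum = {
      d <- cov_decompose(recording)
      a_optimum(recording, groupwise_optimal(d), ...)
    },
    stop(sprintf("unknown scheme '%s'", scheme), call. = FALSE))
}
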