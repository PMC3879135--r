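#' Linear readout weight vector
#'
#' Unit-norm weights applied to the population spike-count vector before a
#' scalar decision. Both the discriminability `A` and the signal-to-noise
#' ratio are invariant under scaling of the weights, so the Euclidean norm
#' is fixed to 1 on construction.
#'
#' @param weights Numeric vector of length N (not all zero).
#' @param scheme One of `"pooling"`, `"best_neuron"`, `"pairwise_optimal"`,
#'   `"groupwise_optimal"`, `"diagonal"`, `"a_optimum"`, `"custom"`.
#' @param trained_state Adaptor amplitude (um) of the recording the weights
#'   were fit on, or `NA` if not applicable.
#' @param trained_trial_ids Optional integer vector of training-trial
#'   indices.
#' @param degenerate Logical flag set by fitters when the problem had no
#'   usable signal.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weights,
                          scheme = "custom",
                          trained_state = NA_real_,
                          trained_trial_ids = NULL,
                          degenerate = FALSE) {
  schemes <- c("pooling", "best_neuron", "pairwise_optimal",
               "groupwise_optimal", "diagonal", "a_optimum", "custom")
  scheme <- match.arg(scheme, schemes)
  weights <- as.numeric(weights)
  if (length(weights) < 1 || any(!is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  structure(
    list(weights = unit_norm(weights), scheme = scheme,
         trained_state = trained_state,
         trained_trial_ids = trained_trial_ids,
         degenerate = isTRUE(degenerate)),
    class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> scheme=%s, N=%d%s\n", x$scheme,
              length(x$weights),
              if (x$degenerate) " (degenerate)" else ""))
  print(round(x$weights, 4))
  invisible(x)
}

as_weights <- function(w, n) {
  v <- if (inherits(w, "weight_vector")) w$weights else as.numeric(w)
  if (length(v) != n)
    stop(sprintf("weight vector has length %d but the population has %d neurons",
                 length(v), n), call. = FALSE)
  v
}

#' Project trials at one stimulus onto a weight vector
#'
#' Each trial's population count vector becomes one scalar: the inner
#' product with the weights.
#'
#' @param recording A [population_recording].
#' @param w A [weight_vector] or numeric vector of length N.
#' @param stimulus Stimulus index in `1..S`.
#' @return Numeric vector of length T (one projection per trial).
#' @export
project <- function(recording, w, stimulus) {
  v <- as_weights(w, n_neurons(recording))
  stimulus <- as.integer(stimulus)
  if (stimulus < 1 || stimulus > n_stimuli(recording))
    stop("invalid stimulus index", call. = FALSE)
  m <- matrix(recording$counts[, stimulus, ], nrow = length(v))
  as.numeric(v %*% m)
}

#' ROC discriminability area between two projection samples
#'
#' Sweeps the decision criterion over every observed projection value
#' (plus infinite anchors); each criterion yields a hit rate
#' `P(a >= c)` and a false-alarm rate `P(b >= c)`. The area under the
#' empirical ROC is computed by the trapezoid rule, and the discriminability
#' is the unsigned area between the curve and the identity line,
#' `A = |AUC - 1/2|`, which ranges from 0 (complete overlap) to 0.5 (no
#' overlap) and is invariant to the sign of the weight vector. With this
#' criterion set and trapezoid rule, `A` equals the tie-corrected
#' Mann-Whitney statistic `|U/(n_a n_b) - 1/2|`.
#'
#' @param proj_a,proj_b Non-empty numeric vectors of projections for the
#'   two stimuli.
#' @return A single number in `[0, 0.5]`.
#' @export
roc_area <- function(proj_a, proj_b) {
  if (length(proj_a) < 1 || length(proj_b) < 1)
    stop("projection samples must be non-empty", call. = FALSE)
  if (any(!is.finite(proj_a)) || any(!is.finite(proj_b)))
    stop("projections must be finite", call. = FALSE)
  crit <- sort(unique(c(proj_a, proj_b)))
  sa <- sort(proj_a); sb <- sort(proj_b)
  na <- length(sa); nb <- length(sb)
  # P(x >= c) via position of c in the sorted sample
  hit <- 1 - findInterval(crit, sa, left.open = TRUE) / na
  fa <- 1 - findInterval(crit, sb, left.open = TRUE) / nb
  # anchors: criterion below all values -> (1,1); above all -> (0,0)
  fa <- c(1, fa, 0); hit <- c(1, hit, 0)
  auc <- sum((fa[-length(fa)] - fa[-1]) * (hit[-length(hit)] + hit[-1]) / 2)
  a <- abs(auc - 0.5)
  min(max(a, 0), 0.5)
}

#' Pairwise discriminability over a whole stimulus set
#'
#' Computes the ROC area `A` for every unordered stimulus pair after
#' projecting onto the weight vector(s), and the overall discriminability:
#' the mean of `A` over all `S(S-1)/2` pairs (66 pairs for the canonical
#' 12-amplitude set).
#'
#' @param recording A [population_recording].
#' @param weights Either a single [weight_vector] (or numeric vector),
#'   applied to every pair, or a list of `S(S-1)/2` weight vectors in
#'   column-major upper-triangle order (`(1,2), (1,3), (2,3), ...`), one
#'   per pair.
#' @return A list of class `discriminability_result` with `pair_A` (S x S
#'   symmetric matrix, `NA` diagonal, amplitude dimnames), `average_A`, and
#'   `n_pairs`.
#' @export
discriminability <- function(recording, weights) {
  s <- n_stimuli(recording)
  if (s < 2) stop("need at least two stimuli", call. = FALSE)
  npair <- s * (s - 1) / 2
  per_pair <- is.list(weights) && !inherits(weights, "weight_vector")
  if (per_pair && length(weights) != npair)
    stop(sprintf("expected 1 or %d weight vectors, got %d",
                 npair, length(weights)), call. = FALSE)
  nn <- n_neurons(recording)
  proj <- if (!per_pair) {
    v <- as_weights(weights, nn)
    lapply(seq_len(s), function(k)
      as.numeric(v %*% matrix(recording$counts[, k, ], nrow = nn)))
  } else NULL
  pair_a <- matrix(NA_real_, s, s,
                   dimnames = list(recording$amplitudes, recording$amplitudes))
  idx <- 0L
  for (j in 2:s) for (i in 1:(j - 1)) {
    idx <- idx + 1L
    if (per_pair) {
      v <- as_weights(weights[[idx]], nn)
      a <- roc_area(as.numeric(v %*% matrix(recording$counts[, i, ], nrow = nn)),
                    as.numeric(v %*% matrix(recording$counts[, j, ], nrow = nn)))
    } else {
      a <- roc_area(proj[[i]], proj[[j]])
    }
    pair_a[i, j] <- pair_a[j, i] <- a
  }
  structure(
    list(pair_A = pair_a,
         average_A = mean(pair_a[upper.tri(pair_a)]),
         n_pairs = npair),
    class = "discriminability_result")
}

#' @export
print.discriminability_result <- function(x, ...) {
  cat(sprintf("<discriminability_result> average A = %.4f over %d stimulus pairs\n",
              x$average_A, x$n_pairs))
  invisible(x)
}

# Average A for a single weight vector; the inner loop of most analyses.
average_a <- function(recording, w) discriminability(recording, w)$average_A
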