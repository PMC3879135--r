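#' Analysis configuration
#'
#' Bundles the knobs of the full analysis grid: which population sizes to
#' sample, how many random neuron selections per size, which decoding
#' schemes to run, and the Monte-Carlo depths of the shuffling and
#' split-half analyses. All stochastic sub-analyses derive their seeds
#' deterministically from `seed`.
#'
#' @param population_sizes Integer vector of population sizes.
#' @param n_selections Random neuron selections per size (each drawn
#'   without replacement, capped by the number of distinct subsets
#'   available; 500 in the canonical full-scale design).
#' @param schemes Character vector of scheme names (see [fit_decoder]).
#' @param n_trial_shuffles Shuffles averaged in [delta_a_shuffled]
#'   (canonically 50).
#' @param n_splits Random half-splits in split-half analyses (canonically
#'   100).
#' @param seed Master integer seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(population_sizes,
                            n_selections = 20,
                            schemes = c("pooling", "groupwise_optimal"),
                            n_trial_shuffles = 50,
                            n_splits = 100,
                            seed = 1) {
  stopifnot(all(population_sizes >= 1), n_selections >= 1,
            n_trial_shuffles >= 1, n_splits >= 1)
  structure(list(population_sizes = as.integer(population_sizes),
                 n_selections = as.integer(n_selections),
                 schemes = schemes,
                 n_trial_shuffles = as.integer(n_trial_shuffles),
                 n_splits = as.integer(n_splits),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# Seeded random neuron selections of a given size, without replacement
# within each selection; capped by the number of distinct subsets.
neuron_selections <- function(n, size, n_selections, seed) {
  n_avail <- suppressWarnings(choose(n, size))
  n_sel <- min(n_selections, n_avail)
  if (size == n) return(list(seq_len(n)))
  with_seed(seed, {
    sel <- list(); tries <- 0L
    while (length(sel) < n_sel && tries < 50L * n_selections) {
      cand <- sort(sample.int(n, size))
      key <- paste(cand, collapse = ",")
      if (is.null(sel[[key]])) sel[[key]] <- cand
      tries <- tries + 1L
    }
    unname(sel)
  })
}

#' Full single-state analysis
#'
#' For each population size and random neuron selection, fits every
#' requested scheme and records the average discriminability on the full
#' recording (training performance) and its split-half test counterpart;
#' additionally computes, per size, the trial-shuffling and
#' diagonal-decoder effects and, for the whole population, the per-pair A
#' matrix, the SCI/NCI, and the signal-noise angle.
#'
#' @param recording A [population_recording].
#' @param config An [analysis_config]. Sizes exceeding the population are
#'   skipped with a warning.
#' @return A list of class `state_report`: `state`, `table` (one row per
#'   size x selection x scheme with `A_train` and `A_test_ratio`),
#'   `delta_table` (per size: mean `delta_a_shuffled` per scheme and
#'   `delta_a_diag`), `pair_A` (full-population groupwise matrix), `sci`,
#'   `nci`, `signal_noise_angle_deg`, `seed`.
#' @export
run_state_analysis <- function(recording, config) {
  n <- n_neurons(recording)
  sizes <- config$population_sizes
  if (any(sizes > n)) {
    warning(sprintf("skipping population sizes above N = %d", n))
    sizes <- sizes[sizes <= n]
  }
  if (length(sizes) == 0) stop("no usable population sizes", call. = FALSE)
  seeds <- child_seeds(config$seed, 3L * length(sizes))
  rows <- list(); drows <- list(); ri <- 0L
  for (z in seq_along(sizes)) {
    size <- sizes[z]
    sels <- neuron_selections(n, size, config$n_selections, seeds[3L * z - 2L])
    dshuf <- stats::setNames(numeric(length(config$schemes)), config$schemes)
    ddiag <- numeric(0)
    for (sel in sels) {
      sub <- subset_neurons(recording, sel)
      for (scheme in config$schemes) {
        w <- fit_decoder(sub, scheme)
        a_train <- discriminability(sub, w)$average_A
        gen <- if (size >= 1 && n_trials(sub) %% 2 == 0)
          split_half_generalization(sub, scheme,
                                    n_splits = min(config$n_splits, 20),
                                    seed = seeds[3L * z - 1L])$ratio
        else NA_real_
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          state = recording$state, size = size,
          selection = paste(sel, collapse = "+"), scheme = scheme,
          A_train = a_train, A_test_ratio = gen)
      }
    }
    # shuffling / diagonal deltas on the first selection of each size
    sub <- subset_neurons(recording, sels[[1]])
    for (scheme in config$schemes)
      dshuf[scheme] <- delta_a_shuffled(sub, scheme,
                                        n_shuffles = config$n_trial_shuffles,
                                        seed = seeds[3L * z])
    ddiag <- if (size >= 2) delta_a_diag(sub) else NA_real_
    drows[[z]] <- data.frame(state = recording$state, size = size,
                             scheme = names(dshuf),
                             delta_a_shuffled_pct = as.numeric(dshuf),
                             delta_a_diag_pct = ddiag)
  }
  d <- cov_decompose(recording)
  structure(list(
    state = recording$state,
    table = do.call(rbind, rows),
    delta_table = do.call(rbind, drows),
    pair_A = discriminability(recording, groupwise_optimal(d))$pair_A,
    sci = signal_correlation_index(recording)$index,
    nci = noise_correlation_index(recording)$index,
    signal_noise_angle_deg = signal_noise_angle(d),
    seed = config$seed), class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat(sprintf("<state_report> adaptor %g um: SCI %.3f, NCI %.3f, %d rows\n",
              x$state, x$sci, x$nci, nrow(x$table)))
  invisible(x)
}

#' Cross-state generalization of the optimal decoder
#'
#' Compares an adaptive decoder (weights re-optimized within the adapted
#' state) with a non-adaptive one (weights carried over from the base
#' state) on matched neurons. Per random half-split: the adaptive decoder
#' is fitted on one half of the adapted trials and evaluated on the other
#' half; the non-adaptive decoder is fitted on the corresponding half of
#' the base-state trials and evaluated on the *same* adapted test half.
#' The ratio `A_nonadaptive / A_adaptive`, averaged over splits, is near 1
#' when adaptation leaves the optimal weights essentially unchanged.
#'
#' Also returns the per-pair discriminability change between the two
#' states' own groupwise decoders (adapted minus base, full trials), the
#' signature of a lateral tuning shift being elevated A above the adaptor
#' amplitude and depressed A below it.
#'
#' @param rec_base Base-state [population_recording] (e.g. non-adapted).
#' @param rec_adapted Adapted-state recording with the same neurons.
#' @param config An [analysis_config] (uses `n_splits`, `seed`).
#' @param scheme Decoding scheme (default groupwise-optimal).
#' @return A list of class `cross_state_result`: `ratio`,
#'   `a_adaptive`, `a_nonadaptive` (per-split), `delta_pair_A` (S x S),
#'   `angular_difference_deg`, `angular_bias_deg` (split-half bias within
#'   the adapted state).
#' @export
cross_state_generalization <- function(rec_base, rec_adapted, config,
                                       scheme = "groupwise_optimal") {
  if (n_neurons(rec_base) != n_neurons(rec_adapted) ||
      !identical(rec_base$neuron_ids, rec_adapted$neuron_ids))
    stop("the two recordings must contain the same neurons", call. = FALSE)
  if (n_trials(rec_base) != n_trials(rec_adapted))
    stop("the two recordings must have matching trial counts", call. = FALSE)
  t <- n_trials(rec_adapted)
  n_splits <- config$n_splits
  seeds <- child_seeds(config$seed, n_splits)
  a_ad <- a_non <- numeric(n_splits)
  for (k in seq_len(n_splits)) {
    sp <- with_seed(seeds[k], half_split(t))
    w_ad <- fit_decoder(subset_trials(rec_adapted, sp$train), scheme)
    w_non <- fit_decoder(subset_trials(rec_base, sp$train), scheme)
    test <- subset_trials(rec_adapted, sp$test)
    a_ad[k] <- discriminability(test, w_ad)$average_A
    a_non[k] <- discriminability(test, w_non)$average_A
  }
  ok <- a_ad > 0
  if (!any(ok))
    stop("adaptive decoder discriminability was zero in every split",
         call. = FALSE)
  d_base <- cov_decompose(rec_base); d_ad <- cov_decompose(rec_adapted)
  pa_base <- discriminability(rec_base, groupwise_optimal(d_base))$pair_A
  pa_ad <- discriminability(rec_adapted, groupwise_optimal(d_ad))$pair_A
  structure(list(
    ratio = mean(a_non[ok] / a_ad[ok]),
    a_adaptive = a_ad, a_nonadaptive = a_non,
    delta_pair_A = pa_ad - pa_base,
    angular_difference_deg = angular_difference(groupwise_optimal(d_base),
                                                groupwise_optimal(d_ad)),
    angular_bias_deg = split_half_bias(rec_adapted, scheme,
                                       n_splits = min(n_splits, 25),
                                       seed = config$seed)),
    class = "cross_state_result")
}

#' @export
print.cross_state_result <- function(x, ...) {
  cat(sprintf(
    "<cross_state_result> non-adaptive/adaptive A ratio = %.3f; angle %.1f deg (bias %.1f)\n",
    x$ratio, x$angular_difference_deg, x$angular_bias_deg))
  invisible(x)
}

#' Decoding-scheme comparison on decorrelated responses
#'
#' Trial-shuffles each recording (eliminating noise correlation among
#' simultaneously recorded neurons), then tabulates average
#' discriminability versus population size for the pairwise-optimal,
#' groupwise-optimal, and pooling schemes. With noise correlation removed,
#' the gap between groupwise and pooling reflects tuning heterogeneity,
#' and pairwise >= groupwise at every size.
#'
#' @param recordings Named list of [population_recording]s (one per state).
#' @param config An [analysis_config] (uses `population_sizes`,
#'   `n_selections`, `seed`).
#' @return A data frame with columns `state`, `size`, `scheme`,
#'   `average_A` (mean over selections).
#' @export
scheme_comparison_decorrelated <- function(recordings, config) {
  if (inherits(recordings, "population_recording"))
    recordings <- list(recordings)
  schemes <- c("pairwise_optimal", "groupwise_optimal", "pooling")
  rows <- list(); ri <- 0L
  seeds <- child_seeds(config$seed, length(recordings))
  for (r in seq_along(recordings)) {
    rec <- trial_shuffle(recordings[[r]], seed = seeds[r])
    n <- n_neurons(rec)
    for (size in config$population_sizes[config$population_sizes <= n]) {
      sels <- neuron_selections(n, size, config$n_selections, seeds[r] + size)
      acc <- stats::setNames(numeric(length(schemes)), schemes)
      for (sel in sels) {
        sub <- subset_neurons(rec, sel)
        for (scheme in schemes) {
          w <- if (size == 1) pooling_weights(1) else fit_decoder(sub, scheme)
          acc[scheme] <- acc[scheme] + discriminability(sub, w)$average_A
        }
      }
      for (scheme in schemes) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(state = rec$state, size = size,
                                 scheme = scheme,
                                 average_A = acc[scheme] / length(sels))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
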