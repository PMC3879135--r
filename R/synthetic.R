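#' Sigmoidal amplitude-tuning parameters
#'
#' One record per neuron. The mean spike count of a neuron at stimulus
#' amplitude `s` (micrometres) is
#' `baseline + gain * plogis((s - midpoint) / slope)`,
#' a logistic (sigmoidal) increase with stimulus intensity. Counts are
#' accumulated over a 50 ms post-stimulus window, so rates are in
#' spikes/trial.
#'
#' @param baseline Spontaneous count, spikes/trial (>= 0).
#' @param gain Amplitude of the evoked increase, spikes/trial (>= 0).
#' @param midpoint Amplitude at half-maximal response, micrometres.
#' @param slope Slope scale of the sigmoid, micrometres (> 0).
#' @return A `data.frame` of class `tuning_params`, one row per neuron.
#' @export
tuning_params <- function(baseline, gain, midpoint, slope) {
  n <- max(length(baseline), length(gain), length(midpoint), length(slope))
  baseline <- rep_len(as.numeric(baseline), n)
  gain <- rep_len(as.numeric(gain), n)
  midpoint <- rep_len(as.numeric(midpoint), n)
  slope <- rep_len(as.numeric(slope), n)
  if (any(baseline < 0) || any(gain < 0))
    stop("baseline and gain must be non-negative", call. = FALSE)
  if (any(slope <= 0)) stop("slope must be positive", call. = FALSE)
  if (any(baseline + gain > 50))
    stop("baseline + gain exceeds 50 spikes per 50 ms window; ",
         "this is beyond a physiological firing rate", call. = FALSE)
  structure(
    data.frame(baseline = baseline, gain = gain,
               midpoint = as.numeric(midpoint), slope = slope),
    class = c("tuning_params", "data.frame"))
}

#' Draw heterogeneous tuning parameters for a synthetic population
#'
#' Emulates the spread of sensitivity thresholds and response gains seen in
#' barrel-cortex amplitude tuning: log-normal baselines and gains, uniform
#' midpoints across the lower two thirds of the 0-33 um stimulus range, and
#' log-normal slope scales.
#'
#' @param n_neurons Number of neurons.
#' @param seed Integer seed.
#' @param midpoint_range Range (um) from which midpoints are drawn uniformly.
#' @param baseline_meanlog,baseline_sdlog,gain_meanlog,gain_sdlog,slope_meanlog,slope_sdlog
#'   Log-normal parameters for baseline and gain (spikes/trial) and slope (um).
#' @return A [tuning_params] data frame with `n_neurons` rows.
#' @export
sample_tuning_params <- function(n_neurons, seed,
                                 midpoint_range = c(6, 21),
                                 baseline_meanlog = log(0.8), baseline_sdlog = 0.5,
                                 gain_meanlog = log(3), gain_sdlog = 0.5,
                                 slope_meanlog = log(3), slope_sdlog = 0.4) {
  stopifnot(n_neurons >= 1)
  with_seed(seed, {
    tuning_params(
      baseline = pmin(stats::rlnorm(n_neurons, baseline_meanlog, baseline_sdlog), 10),
      gain = pmin(stats::rlnorm(n_neurons, gain_meanlog, gain_sdlog), 30),
      midpoint = stats::runif(n_neurons, midpoint_range[1], midpoint_range[2]),
      slope = stats::rlnorm(n_neurons, slope_meanlog, slope_sdlog))
  })
}

#' Trial-to-trial noise model
#'
#' Spike counts are generated through a Gaussian copula: a latent
#' multivariate normal with uniform pairwise correlation is mapped per
#' neuron and stimulus through the Poisson (Fano factor 1) or
#' negative-binomial (Fano factor > 1) quantile function. The
#' negative-binomial size is chosen per mean so that Var = fano * mean at
#' every stimulus.
#'
#' @param fano_factor Target Fano factor (variance/mean) of the counts,
#'   >= 1. Underdispersed counts (Fano < 1) are not supported.
#' @param rho Latent pairwise correlation shared by all neuron pairs, in
#'   `[0, 1)`.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(fano_factor = 1.5, rho = 0.1) {
  if (!is.numeric(fano_factor) || fano_factor < 1)
    stop("fano_factor must be >= 1 (underdispersed counts unsupported)",
         call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  structure(list(fano_factor = as.numeric(fano_factor), rho = as.numeric(rho)),
            class = "noise_model")
}

#' Adaptation state specification
#'
#' Adaptation to a preceding vibration is modeled as (i) a lateral shift of
#' every tuning-curve midpoint by `tuning_shift` micrometres, (ii) an
#' `alignment` contraction of the midpoints about their shifted population
#' mean -- adaptation tends to equalize neuronal thresholds by aligning
#' response functions relative to the adaptor, which is what raises signal
#' correlation -- and (iii) an additive increment to the latent pairwise
#' noise correlation. Response saturation levels (baseline, gain) are left
#' untouched. The non-adapted state (adaptor 0) must have no shift, no
#' alignment and no correlation increment.
#'
#' @param adaptor_amplitude Adaptor amplitude, micrometres (0, 6 or 12 in
#'   the canonical design).
#' @param tuning_shift Lateral midpoint shift, micrometres.
#' @param rho_increment Added to the noise model's pairwise `rho` (>= 0).
#' @param alignment Fractional contraction of midpoint dispersion in
#'   `[0, 1]`; 0 leaves midpoint spread unchanged.
#' @return A list of class `adaptation_spec`.
#' @export
adaptation_spec <- function(adaptor_amplitude = 0,
                            tuning_shift = adaptor_amplitude,
                            rho_increment = 0,
                            alignment = 0) {
  if (rho_increment < 0) stop("rho_increment must be >= 0", call. = FALSE)
  if (alignment < 0 || alignment > 1)
    stop("alignment must lie in [0, 1]", call. = FALSE)
  if (adaptor_amplitude == 0 &&
      (tuning_shift != 0 || rho_increment != 0 || alignment != 0))
    stop("the non-adapted state (adaptor 0) must have tuning_shift = 0, ",
         "rho_increment = 0 and alignment = 0", call. = FALSE)
  structure(list(adaptor_amplitude = as.numeric(adaptor_amplitude),
                 tuning_shift = as.numeric(tuning_shift),
                 rho_increment = as.numeric(rho_increment),
                 alignment = as.numeric(alignment)),
            class = "adaptation_spec")
}

# Mean-count matrix (N x S) implied by tuning + adaptation.
tuning_mean_matrix <- function(tuning, adapt, amplitudes) {
  mids <- tuning$midpoint + adapt$tuning_shift
  if (adapt$alignment > 0)
    mids <- mean(mids) + (1 - adapt$alignment) * (mids - mean(mids))
  t(vapply(seq_len(nrow(tuning)), function(i) {
    tuning$baseline[i] +
      tuning$gain[i] * stats::plogis((amplitudes - mids[i]) / tuning$slope[i])
  }, numeric(length(amplitudes))))
}

#' Generate a synthetic population recording
#'
#' Draws `n_trials` spike-count vectors at each stimulus amplitude from a
#' Gaussian-copula count model: latent N(0, Sigma) with
#' `Sigma = (1 - rho) I + rho J` (rho = `noise$rho + adapt$rho_increment`),
#' mapped through the Poisson or negative-binomial quantile with the
#' sigmoid-derived mean. Identical seeds give bitwise-identical counts.
#'
#' @param tuning A [tuning_params] data frame (one row per neuron).
#' @param noise A [noise_model].
#' @param adapt An [adaptation_spec].
#' @param amplitudes Stimulus amplitudes in micrometres; default the
#'   canonical 12-amplitude grid 0-33 um in 3 um steps.
#' @param n_trials Trials per stimulus (>= 2), default 100.
#' @param seed Integer seed (required).
#' @param unit_kind Per-neuron `"single"`/`"multi"` flags.
#' @return A [population_recording].
#' @export
generate_population <- function(tuning, noise = noise_model(),
                                adapt = adaptation_spec(0),
                                amplitudes = seq(0, 33, by = 3),
                                n_trials = 100, seed,
                                unit_kind = NULL) {
  if (!inherits(tuning, "tuning_params")) tuning <- as_tuning(tuning)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- nrow(tuning)
  if (n < 1) stop("need at least one neuron", call. = FALSE)
  if (n_trials < 2) stop("need n_trials >= 2", call. = FALSE)
  rho <- noise$rho + adapt$rho_increment
  if (rho >= 1)
    stop(sprintf(
      "implied latent correlation %.3f is not < 1; the uniform-correlation ",
      rho), "latent covariance would not be positive definite", call. = FALSE)
  mu <- tuning_mean_matrix(tuning, adapt, amplitudes)
  s <- length(amplitudes)
  fano <- noise$fano_factor
  counts <- with_seed(seed, {
    out <- array(0L, dim = c(n, s, n_trials))
    # chol of (1-rho) I + rho J; n = 1 degenerates to 1x1
    sig <- matrix(rho, n, n); diag(sig) <- 1
    ch <- chol(sig)
    for (k in seq_len(s)) {
      z <- matrix(stats::rnorm(n_trials * n), n_trials, n) %*% ch
      u <- stats::pnorm(z)
      for (i in seq_len(n)) {
        m <- mu[i, k]
        out[i, k, ] <- if (m <= 0) {
          0L
        } else if (fano == 1) {
          as.integer(stats::qpois(u[, i], lambda = m))
        } else {
          as.integer(stats::qnbinom(u[, i], size = m / (fano - 1), mu = m))
        }
      }
    }
    out
  })
  population_recording(counts, amplitudes,
                       state = adapt$adaptor_amplitude,
                       unit_kind = unit_kind)
}

as_tuning <- function(x) {
  need <- c("baseline", "gain", "midpoint", "slope")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("tuning must be a tuning_params data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tuning_params(x$baseline, x$gain, x$midpoint, x$slope)
}

#' Generate the three-state adaptation series
#'
#' One recording per adaptation state (canonically adaptors 0, 6 and 12 um)
#' from shared tuning parameters; only the adaptation specification differs
#' across states. Per-state child seeds are derived deterministically from
#' `seed`.
#'
#' @inheritParams generate_population
#' @param adaptors Adaptor amplitudes, one per state.
#' @param shifts Lateral tuning shifts (um), one per state.
#' @param rho_increments Noise-correlation increments, one per state.
#' @param alignments Midpoint alignment fractions, one per state.
#' @return A named list of [population_recording]s, names `"state_<adaptor>"`.
#' @export
generate_adaptation_series <- function(tuning, noise = noise_model(),
                                       adaptors = c(0, 6, 12),
                                       shifts = adaptors,
                                       rho_increments = c(0, 0.05, 0.10)[seq_along(adaptors)],
                                       alignments = c(0, 0.3, 0.5)[seq_along(adaptors)],
                                       amplitudes = seq(0, 33, by = 3),
                                       n_trials = 100, seed) {
  k <- length(adaptors)
  if (length(shifts) != k || length(rho_increments) != k ||
      length(alignments) != k)
    stop("adaptors, shifts, rho_increments and alignments must have equal ",
         "lengths", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  seeds <- child_seeds(seed, k)
  out <- lapply(seq_len(k), function(j) {
    generate_population(
      tuning, noise,
      adapt = adaptation_spec(adaptors[j], tuning_shift = shifts[j],
                              rho_increment = rho_increments[j],
                              alignment = alignments[j]),
      amplitudes = amplitudes, n_trials = n_trials, seed = seeds[j])
  })
  names(out) <- paste0("state_", adaptors)
  out
}
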