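#' Population spike-count recording
#'
#' The universal input container: a non-negative integer spike-count tensor
#' of dimension neurons x stimuli x trials, together with the stimulus
#' amplitudes (micrometres), an adaptation-state label (the adaptor
#' amplitude), and a per-neuron unit type.
#'
#' @param counts Integer array `[N, S, T]` of spike counts (>= 0).
#' @param amplitudes Strictly increasing numeric vector of length `S`,
#'   stimulus amplitudes in micrometres.
#' @param state Adaptor amplitude in micrometres labelling the adaptation
#'   state of the whole recording (0 for non-adapted).
#' @param unit_kind Character vector of length `N`, each `"single"` or
#'   `"multi"`.
#' @param neuron_ids Character vector of length `N` of unit identifiers.
#'
#' @return An object of class `population_recording`: a list with elements
#'   `counts`, `amplitudes`, `state`, `unit_kind`, `neuron_ids`.
#' @export
population_recording <- function(counts, amplitudes,
                                 state = 0,
                                 unit_kind = NULL,
                                 neuron_ids = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array [neurons x stimuli x trials]",
         call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("`counts` must contain non-negative integers", call. = FALSE)
  n <- dim(counts)[1L]; s <- dim(counts)[2L]; t <- dim(counts)[3L]
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != s)
    stop("length(amplitudes) must equal dim(counts)[2]", call. = FALSE)
  if (s > 1 && any(diff(amplitudes) <= 0))
    stop("`amplitudes` must be strictly increasing", call. = FALSE)
  unit_kind <- unit_kind %||% rep("single", n)
  if (length(unit_kind) != n || !all(unit_kind %in% c("single", "multi")))
    stop("`unit_kind` must be length-N with values 'single'/'multi'",
         call. = FALSE)
  neuron_ids <- neuron_ids %||% sprintf("n%02d", seq_len(n))
  if (length(neuron_ids) != n || anyDuplicated(neuron_ids))
    stop("`neuron_ids` must be N unique identifiers", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, amplitudes = amplitudes, state = as.numeric(state),
         unit_kind = unit_kind, neuron_ids = as.character(neuron_ids)),
    class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<population_recording> %d neurons x %d stimuli x %d trials\n", d[1], d[2], d[3]))
  cat(sprintf("  amplitudes: %s um\n",
              paste(format(x$amplitudes, trim = TRUE), collapse = ", ")))
  cat(sprintf("  adaptation state: %g um adaptor; units: %d single, %d multi\n",
              x$state, sum(x$unit_kind == "single"), sum(x$unit_kind == "multi")))
  invisible(x)
}

#' Number of neurons, stimuli or trials in a recording
#' @param recording A [population_recording].
#' @return Integer count.
#' @export
n_neurons <- function(recording) dim(recording$counts)[1L]

#' @rdname n_neurons
#' @export
n_stimuli <- function(recording) dim(recording$counts)[2L]

#' @rdname n_neurons
#' @export
n_trials <- function(recording) dim(recording$counts)[3L]

#' Subset a recording by neurons or by trials
#'
#' Trial subsetting keeps the same trial indices at every stimulus, which is
#' how split-half analyses partition the data.
#'
#' @param recording A [population_recording].
#' @param neurons Integer indices of neurons to keep.
#' @param trials Integer indices of trials to keep.
#' @return A [population_recording] restricted to the selection.
#' @export
subset_neurons <- function(recording, neurons) {
  neurons <- as.integer(neurons)
  if (length(neurons) < 1 || any(neurons < 1 | neurons > n_neurons(recording)))
    stop("invalid neuron indices", call. = FALSE)
  population_recording(
    recording$counts[neurons, , , drop = FALSE], recording$amplitudes,
    state = recording$state, unit_kind = recording$unit_kind[neurons],
    neuron_ids = recording$neuron_ids[neurons])
}

#' @rdname subset_neurons
#' @export
subset_trials <- function(recording, trials) {
  trials <- as.integer(trials)
  if (length(trials) < 2 || any(trials < 1 | trials > n_trials(recording)))
    stop("need at least two valid trial indices", call. = FALSE)
  population_recording(
    recording$counts[, , trials, drop = FALSE], recording$amplitudes,
    state = recording$state, unit_kind = recording$unit_kind,
    neuron_ids = recording$neuron_ids)
}

# Mean count of each neuron at each stimulus (N x S).
stimulus_means <- function(recording) {
  apply(recording$counts, c(1L, 2L), mean)
}
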