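# Shared fixtures, built in code at test time.

# A heterogeneous correlated population with the canonical stimulus grid.
make_pop <- function(n = 6, seed = 101, rho = 0.2, fano = 1.5,
                     n_trials = 60, amplitudes = seq(0, 33, by = 3),
                     shift = 0, rho_increment = 0, alignment = 0) {
  tp <- sample_tuning_params(n, seed = seed)
  adapt <- if (shift == 0 && rho_increment == 0 && alignment == 0)
    adaptation_spec(0)
  else
    adaptation_spec(adaptor_amplitude = shift, tuning_shift = shift,
                    rho_increment = rho_increment, alignment = alignment)
  generate_population(tp, noise_model(fano_factor = fano, rho = rho),
                      adapt = adapt, amplitudes = amplitudes,
                      n_trials = n_trials, seed = seed + 1)
}

# Flat-tuned, uncorrelated Poisson population: the null for index tests.
make_null_pop <- function(n, seed, n_stimuli = 12, n_trials = 100,
                          rate = 5) {
  tp <- tuning_params(baseline = rep(rate, n), gain = 0,
                      midpoint = 15, slope = 3)
  generate_population(tp, noise_model(fano_factor = 1, rho = 0),
                      amplitudes = seq(0, by = 3, length.out = n_stimuli),
                      n_trials = n_trials, seed = seed)
}

# Brute-force tie-corrected Mann-Whitney discriminability oracle:
# counts pairs with half credit for ties, independently of the ROC sweep.
mw_area_oracle <- function(a, b) {
  u <- 0
  for (x in a) u <- u + sum(x > b) + 0.5 * sum(x == b)
  abs(u / (length(a) * length(b)) - 0.5)
}

# Build a recording directly from a count tensor with default labels.
rec_from_counts <- function(counts, amplitudes = NULL) {
  s <- dim(counts)[2]
  population_recording(counts,
                       amplitudes %||% seq(0, by = 3, length.out = s))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

unit_norm_test <- function(x) x / sqrt(sum(x^2))

# Two tuning subgroups (low- and high-threshold neurons): gives the decoding
# problem a strong second eigen-dimension, as in populations with spread
# sensitivity thresholds.
make_two_group_pop <- function(seed, n_trials = 100) {
  tp <- popdecode::tuning_params(
    baseline = with_seed_helper(seed, runif(6, 0.5, 1.5)),
    gain = with_seed_helper(seed + 1, runif(6, 2.5, 5)),
    midpoint = c(with_seed_helper(seed + 2, runif(3, 6, 10)),
                 with_seed_helper(seed + 3, runif(3, 20, 24))),
    slope = with_seed_helper(seed + 4, runif(6, 2.5, 4)))
  generate_population(tp, noise_model(fano_factor = 1.5, rho = 0.25),
                      n_trials = n_trials, seed = seed + 5)
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
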