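---
title: "Methods: optimal linear decoding of population spike counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal linear decoding of population spike counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdecode)
```

## Scope

`popdecode` quantifies how well a linear readout of population spike
counts discriminates stimulus amplitudes, and how that performance depends
on the readout weights, on trial-to-trial (noise) and tuning (signal)
correlations, and on sensory adaptation. This vignette is the package's
account of the underlying models, the choices made where several
formulations were defensible, and what the synthetic-data tests do and do
not establish about real recordings.

## Discriminability: criterion-sweep ROC area

For one stimulus pair, each trial's population count vector is projected
onto a weight vector, and a decision criterion is swept over every
observed projection value (with infinite anchors at both ends). Each
criterion yields a hit rate and a false-alarm rate; the empirical ROC is
integrated by the trapezoid rule, and the discriminability is the unsigned
area between the curve and the identity line, `A = |AUC − 1/2| ∈ [0, 0.5]`.

Three consequences of this construction are worth stating:

* With criteria at the observed values and `≥`-thresholding, the sweep
  reproduces the tie-corrected Mann–Whitney statistic exactly:
  `A = |U/(n_a n_b) − 1/2|` with ties counted half. The test suite asserts
  this identity against an independent pair-counting oracle on a thousand
  random instances.
* Taking the *unsigned* area makes `A` invariant to the sign (and scale)
  of the weight vector. An arbitrary sign flip would otherwise move the
  empirical curve below the diagonal; with the unsigned convention the
  question of which stimulus anchors the hit rate is immaterial.
* `A` for a whole stimulus set is the unweighted mean over all
  `S(S−1)/2` unordered pairs (66 for the canonical 12-amplitude grid).

## The decoding schemes

The groupwise-optimal decoder maximizes
`SNR(w) = (wᵀ Σ_s w)/(wᵀ Σ_n w)`, where `Σ_s` is the sample covariance of
the per-stimulus mean responses about the grand mean (divisor `S − 1`) and
`Σ_n` the per-stimulus trial covariance (divisor `T − 1`) averaged over
stimuli with equal weights (trial counts are equal by design; for a single
pair the pooled covariance is likewise the two-matrix mean). The objective
is scale-invariant, so the covariance divisor conventions have no effect
on the solution; they are documented for reproducibility.

The maximizer is the top generalized eigenvector of `(Σ_s, Σ_n)`. It is
computed in symmetric whitened form — with `W = Σ_n^{−1/2}` (symmetric
eigen square root), the leading eigenvector `v` of `W Σ_s W` gives
`w = W v` — rather than by literally inverting `Σ_n`, which is the
numerically stable route to the same solution. Numerical choices:

* **Silent neurons.** Neurons with zero average spike count make `Σ_n`
  singular; they are excluded from the solve and assigned weight exactly
  zero.
* **Residual singularity.** If the active-neuron noise covariance is still
  singular (e.g. a neuron with constant counts), a ridge of
  `10⁻⁸ · trace/N` is added before whitening.
* **Sign canonicalization.** `w` is flipped so the strongest stimulus
  projects above the weakest (`A` is unaffected; output is reproducible).
* **Degenerate signal.** A zero signal covariance (no tuning at all)
  returns uniform weights flagged `degenerate`, with a warning, rather
  than an arbitrary eigenvector of noise.

The pairwise-optimal decoder uses the familiar two-class closed form
`w ∝ Σ_pooled⁻¹ (μ_i − μ_j)` per stimulus pair; it needs to know which
pair is being discriminated, so it is an upper bound rather than a
biologically plausible scheme. Pooling (equal weights), best-neuron
(indicator of the unit with the highest single-unit average `A`; ties go
to the lowest index), and the diagonal decoder (groupwise solution after
zeroing off-diagonal noise covariance — i.e. a decoder optimized as if
neurons were uncorrelated, applied to the true correlated responses)
complete the comparison set.

`a_optimum` refines the groupwise solution by maximizing average `A`
itself with a coordinate pattern search (probe each coordinate at
`±step`, halve the step when no probe improves, stop below `10⁻³` or at
the evaluation budget, default initial step 0.1). The method is cited in
the decoding literature without settings; these defaults were chosen for
determinism and are exposed as arguments. With a zero budget the start
vector is returned unchanged with `status = "budget_exhausted"`.

## Signal and noise correlation indices

Both indices are the bias-corrected, `N`-normalized leading eigenvalue of
a correlation matrix: across-stimulus tuning-curve correlations for the
signal index (SCI), stimulus-averaged trial correlations for the noise
index (NCI). Because the correlation matrix of `N` curves sampled at `S`
points has rank at most `min(N, S−1)`, the normalized leading eigenvalue
has floor `b = 1/min(N, S−1)`; subtracting `b` and rescaling by `1 − b`
maps the index to `[0, 1]` independently of population size (the NCI uses
`b = 1/min(N, T−1)`). For `N = 2` this reduces exactly to the absolute
Pearson correlation between the two tuning curves (SCI) or the absolute
mean trial-by-trial correlation (NCI).

Handling of degenerate input: neurons with constant tuning are excluded
from the SCI (their z-score is undefined) with a warning, and the retained
count enters the bias term; a neuron with zero variance at *some* stimulus
contributes zero correlations at that stimulus for the NCI; eigenvalues
are clipped at zero before normalization to absorb floating-point
negatives, and the final index is clipped to `[0, 1]`.

A finite-sample caveat documented deliberately: the rank-floor correction
removes the *structural* bias, not the *sampling* bias. Two independent
random 12-point tuning curves have `E|r| ≈ 0.25`, so the null SCI at the
canonical `S = 12` grid is materially positive for any `N`. The null-bias
tests in the suite therefore use a fine stimulus grid (`S = 100`), where
the sampling bias becomes negligible for all tested population sizes; at
`S = 12` users should compare observed indices against a
stimulus-shuffled reference (`stimulus_shuffle`), not against zero.

`trial_shuffle` permutes each neuron's trial order independently within
each stimulus: per-neuron count multisets, per-stimulus means, and hence
the SCI are preserved exactly, while cross-neuron covariation is
destroyed. `stimulus_shuffle` permutes each neuron's stimulus labels
independently; note that for simultaneously recorded populations this also
re-pairs trials across stimulus blocks and therefore destroys noise
correlation along with tuning alignment — it is a control for the SCI, not
an NCI-preserving operation.

`ΔA_shuffled` is the percent change in average `A` when a scheme is
optimized and evaluated on trial-shuffled rather than true responses
(averaged over shuffles; 50 in the full-scale design); `ΔA_diag` is the
percent change of the diagonal relative to the full groupwise decoder on
the true responses. Both are signed: negative `ΔA_diag` is the cost of
ignoring noise correlation ("a drop of 5%" corresponds to −5).

## Weight-perturbation geometry

The generalized eigenvectors of `(Σ_s, Σ_n)` rank activity directions by
signal-to-noise, but they are not orthogonal in neuron space.
`orthogonalized_eigenbasis` applies Gram–Schmidt in descending-eigenvalue
order, giving an orthonormal basis whose first vector is exactly the
optimal direction; rank-lost directions are completed arbitrarily within
the remaining subspace.

`rotation_toward_identity` rotates the optimal direction toward the
identity line along the two asymmetric great-circle arcs that cover the
full 180°; both endpoints are collinear with the identity line and are
evaluated with the exact identity vector, so their performance matches
pooling bit-for-bit (a deliberate guard against floating-point
perturbation of ROC tie structure). Because the optimal direction is
generally not perpendicular to the identity line, performance dips near
the point of maximal deviation, close to 90°.

`rotation_toward_dimensions` follows the whitened-coordinates convention:
the rotation mixes the leading whitened eigenvector with each other
whitened eigenvector and maps back to neuron space. In these coordinates
`SNR(θ) = cos²θ·λ₁ + sin²θ·λ_k`, so the SNR cost of a deviation is
ordered by the target dimension's eigenvalue at *every* angle. The
corresponding ordering in measured `A` is clear at large angles
everywhere, but at small angles (e.g. 30°) it is only statistically
detectable when the second eigen-dimension carries substantial signal
(`λ₂/λ₁` of order 0.3, as in populations with two groups of sensitivity
thresholds); with a near-degenerate tail spectrum the 30° costs of all
directions coincide to within per-pair interference noise. The test suite
uses two-subgroup populations for the small-angle ordering and the default
generator for the large-angle ordering.

Angular differences between weight vectors are `acos(w₁ · w₂)` on
sign-canonicalized unit vectors. Because this measure is non-negative, the
mean angle between weights fitted on complementary trial halves of the
*same* recording (`split_half_bias`, 100 random halvings by default)
estimates the positive estimation bias to subtract from cross-state
comparisons.

## Synthetic populations

The generator produces integer count tensors with controlled tuning,
dispersion, correlation, and adaptation structure:

* **Tuning**: logistic ("sigmoidal") amplitude tuning,
  `baseline + gain · logistic((s − midpoint)/slope)` — the simplest
  saturating form with interpretable midpoint/slope parameters. Means are
  non-decreasing in amplitude by construction.
* **Counts**: a Gaussian copula maps a latent `N(0, Σ_ρ)` draw, with
  `Σ_ρ = (1−ρ)I + ρJ` (uniform latent correlation, positive definite for
  `ρ ∈ [0, 1)`), through the Poisson quantile (Fano factor 1) or the
  negative-binomial quantile with per-mean size `m/(fano−1)` (Fano > 1,
  constant across stimuli). Underdispersed counts (Fano < 1) have no clean
  quantile counterpart and are rejected at validation. The copula is a
  modeling stand-in: real spike-count distributions are not specified by
  any of the summary statistics the analyses use, and the generator makes
  no claim beyond matching means, Fano factor, and pairwise correlation.
* **Heterogeneity** (`sample_tuning_params`): log-normal baselines
  (median 0.8 spikes/trial), gains (median 3), slopes (median 3 µm), and
  uniform midpoints on 6–21 µm — spike-count scales typical of a 50 ms
  cortical window and sensitivity thresholds spread over the lower two
  thirds of the 0–33 µm stimulus range.
* **Adaptation** (`adaptation_spec`): a lateral midpoint shift by the
  adaptor amplitude, an `alignment` contraction of the midpoints about
  their shifted mean, and an additive increment to the latent correlation
  (defaults 0/0.05/0.10 for 0/6/12 µm adaptors, alignment 0/0.3/0.5).
  Saturation levels are untouched. The alignment term deserves a note: a
  *purely* translational shift moves every tuning curve toward its
  low-signal tail on a fixed stimulus grid and so tends to *reduce* the
  measured signal correlation at finite trial counts. What raises signal
  correlation in adapted cortex is the equalization of thresholds —
  response functions aligning relative to the adaptor — and the alignment
  parameter implements exactly that contraction. With it, adapted states
  show reliably higher SCI (and, via the ρ increment, higher NCI), which
  is the regime the cross-adaptation analyses assume.

Every stochastic operation takes an explicit integer seed and derives any
child seeds deterministically; no global RNG state is consumed or left
behind.

## Cross-adaptation analyses

`cross_state_generalization` compares, on matched neurons and per random
trial-half: an *adaptive* decoder (fitted on one half of the adapted
trials, tested on the other half) against a *non-adaptive* decoder (fitted
on the corresponding half of the base-state trials, tested on the same
adapted test half — the test half is shared so the comparison differs only
in the training state). Under lateral-shift adaptation the ratio is near
1: the weights that separate amplitude pairs in the non-adapted state
separate the shifted pairs equally well. The per-pair `ΔA` matrix
(adapted minus base, each state's own groupwise decoder) shows the
signature of the shift — elevated discriminability for pairs above the
adaptor amplitude and depressed below it. An adaptation that scrambles
which neuron carries which tuning breaks the generalization, which is the
adversarial control in the test suite.

## Problem sizes and what the tests show

The shipped tests and the acceptance script run populations of 2–16
neurons, 12 (or up to 100, for null-bias checks) stimuli, and 20–100
trials, with tens of shuffles/splits — sizes at which every analysis
completes in seconds while leaving the Monte-Carlo error well inside the
asserted margins. The full-scale design the defaults mirror (500 neuron
selections per size, 50 trial shuffles, 100 trial halvings, populations up
to 73 units) is reachable by raising the corresponding `analysis_config`
fields.

Passing tests establish that the estimators and optimizers implement their
definitions (oracle identities, eigen residuals, closed forms), and that
the qualitative phenomena — optimal ≥ pooling, shuffling helps pooling,
adaptation raises correlation indices and preserves decoder direction —
hold under the generator's assumptions: uniform latent correlation, exact
logistic tuning, stationary trials. They do not certify behavior under
real-data features the generator omits: non-stationarity and slow drifts,
heterogeneous or stimulus-dependent correlation structure, non-monotone
tuning, or spike-sorting artifacts. For real recordings the shuffling
controls and split-half bias estimates are the package's built-in guards
against over-reading structure that sampling noise can produce.

## Known limitations

* Decoding uses only the first generalized eigenvector; multi-dimensional
  readouts over later eigenvectors are out of scope.
* No parametric (binormal) ROC fit and no confidence intervals on `A`;
  resampling is left to the caller.
* The `A`-optimum pattern search is local; it refines the groupwise
  solution rather than guaranteeing a global optimum of the non-smooth
  average-`A` surface.
* The SCI/NCI sampling bias at small `S` is documented, not corrected;
  use stimulus-shuffled references at the canonical grid.
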