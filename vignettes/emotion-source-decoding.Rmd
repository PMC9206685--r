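---
title: "Decoding emotional state from EEG in source space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding emotional state from EEG in source space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emosource)
```

## The problem

Scalp EEG has excellent temporal resolution but poor spatial resolution:
the potential at each electrode mixes contributions from many cortical
territories.  Emotional states, however, engage reasonably specific
territories — positive and negative stimulation activate different regions
of the temporal and occipital cortex — so a decoder that first *unmixes*
the scalp recording into cortical source signals, and then classifies the
pattern of activity across those sources, can exploit spatial structure
that a sensor-space classifier cannot see.

`emosource` implements that chain end to end:

1. **Forward model.**  A single time sample obeys `y = H x + e`, with `y`
   the N sensor potentials, `H` the N × M lead field, `x` the M dipole
   amplitudes and `e` white Gaussian noise of variance σ².  N < M always
   (under-determined inverse problem).
2. **sLORETA initialization.**  The Tikhonov minimum-norm estimate
   `T y` standardized by the resolution-matrix diagonal.  For a noiseless
   single source the standardized power peaks exactly at the true source,
   which makes it a trustworthy initializer.
3. **Sparse Bayesian inversion.**  A Bernoulli–Laplace (spike-and-slab)
   prior on each amplitude, a Jeffreys prior on σ², and a Gibbs sampler
   over all unknowns.  The posterior inclusion probabilities give the
   active support; restricted least squares gives the time courses.
4. **Graph construction.**  High-power sources become graph nodes; edge
   weights are (absolute) Pearson correlations of the source time courses,
   thresholded at β.
5. **DGCNN classification.**  Chebyshev spectral graph filters, a 1×1
   convolution, and a dense softmax head — with the adjacency matrix itself
   updated during training (the "dynamic" in DGCNN).

## The spike-and-slab posterior and its Gibbs sampler

Each amplitude has prior
`f(x_i | ω, λ) = (1 − ω) δ(x_i) + ω/(2λ) exp(−|x_i|/λ)`:
a point mass at zero with weight 1 − ω (the ℓ₀ part) and a Laplace slab of
scale λ (the ℓ₁ part).  Conditioned on everything else, `x_i` follows a
three-component mixture — spike, positively truncated Gaussian, negatively
truncated Gaussian — whose weights involve factors
`exp(μ±²/2σᵢ²)`.  These overflow catastrophically whenever a source is
well supported by the data, so all weights are computed in the log domain
with `pnorm(log.p = TRUE)` for the Gaussian tail mass and combined by
log-sum-exp; a property test drives |μ±|/σᵢ up to 50 and checks the
weights still normalize exactly.

The hyperparameter conditionals are not uniquely determined by the model
statement; we use the standard conjugate choices and unit-test each against
its closed-form moments:

* `σ² | y, x ~ InvGamma(N/2, ‖y − Hx‖²/2)` (implied by the Jeffreys prior),
  floored at a configurable ε so noiseless data cannot collapse the chain;
* `ω | x ~ Beta(1 + n₁, 1 + M − n₁)` under a uniform prior, with
  `n₁ = #{i : x_i ≠ 0}` counted by *exact* zeros — only the spike produces
  them, so no epsilon is involved;
* `λ | x ~ InvGamma(a₀ + n₁, b₀ + Σ|x_i|)` under a weak proper
  InvGamma(1, 1) prior, which is also the fallback when n₁ = 0.

Truncated-Gaussian draws use the inverse CDF in the bulk and a
shifted-exponential rejection sampler when the truncation point is more
than six standard deviations into the tail.  The sweep updates coordinates
in fixed index order (a random-scan flag exists), then σ², λ, ω.  The
compiled sweep and a pure-R reference implementation consume the same RNG
stream and agree draw for draw — that equivalence is itself a test.

Chains default to 2000 sweeps with 500 burn-in.  The per-epoch localizer
runs shorter chains (600/200) on a handful of uniformly spaced time
snapshots, averages their inclusion probabilities, fixes the merged
support, and recovers full time courses by least squares restricted to the
support — exact for noiseless data whenever the support is correct, and far
cheaper than per-sample MCMC.

## The classifier

Node features are the raw source time courses (an optional band-power mode
was considered and rejected: per-node power is blind to the cross-node
coherence structure that distinguishes connectivity-defined classes).  The
graph filter computes `z = Σ_k θ_k T_k(L̃) x` by the three-term Chebyshev
recursion on the rescaled Laplacian `L̃ = 2L/λmax − I`; no
eigendecomposition ever happens on the training path (eigensolves appear
only in the graph-Fourier utilities and in test oracles).  λmax is
recomputed exactly after every adjacency change; graphs here have at most
a few dozen nodes, so a dense eigensolve is cheap.

The adjacency update is the relaxation
`W* ← (1 − ρ) W* + ρ ∂Loss/∂W*`.  As written this *ascends* the loss; the
default mode negates the gradient term so training reduces the loss, and a
`literal` mode preserves the printed sign for fidelity.  After every update
the matrix is symmetrized and clamped to nonnegative entries, keeping the
Laplacian positive semidefinite.  The gradient with respect to the
adjacency is obtained by reverse accumulation through the Chebyshev
recursion, holding λmax fixed within a batch.

Defaults: K = 3 polynomial orders, 16 graph-filter features, a 32-map 1×1
convolution, ρ = 10⁻³, batch size 16.  Two training choices deserve
comment because the pipeline's defaults differ from the bare
`train_config()` defaults (lr 10⁻³, 100 epochs):

* **lr = 3·10⁻³ and 200 epochs.**  With 40 training epochs per split,
  100 epochs of SGD at lr 10⁻³ reaches perfect training accuracy but with
  thin margins; the longer, slightly faster schedule converges the decision
  boundary properly.
* **Circular time-shift augmentation and weight decay 10⁻².**  Oscillatory
  epochs carry arbitrary phase.  Without augmentation the filter
  coefficients memorize the phases of the individual training epochs and
  generalization collapses on any task whose cue is second-order (band or
  correlation structure rather than per-node amplitude).  Shifting every
  node of an epoch by one common random offset per presentation preserves
  band content and cross-node correlations exactly while destroying phase
  identity; weight decay is applied to filter, convolution and dense
  weights but never to the adjacency.

## What the synthetic generator emulates — and what it does not

`emotion_dataset_spec()` defines a two-class music/video-style stimulation
experiment: 10 subjects × 10 trials by default, 32 sensors, 200 candidate
sources, 8 s epochs at 128 Hz, sensor SNR 15 dB.  Each class activates a
sparse source set (three disjoint sources per class by default, echoing the
observation that positive and negative stimulation engage different
cortical territories); active sources oscillate in a class-specific band
(alpha 8–12 Hz for positive, theta 4–8 Hz for negative) under an AR(1)
envelope, with within-class pairwise correlation 0.7 by construction
(`x_j = √ρ·s + √(1−ρ)·d_j` against a shared unit-variance component).  An
optional `correlation_groups` field restricts the shared component to
subgroups of the active set, which is how connectivity-discriminative
datasets (identical active sets, class-distinct coherence) are built.

The lead field is synthetic: either unit-column random Gaussian (default —
scale-free, well conditioned) or a single-sphere analytic model with
radial dipoles on Fibonacci lattices.  Neither reproduces real head
geometry, skull conductivity, cortical folding, or realistic inter-subject
variability; electrode placements do not follow the 10–20 system; noise is
white, whereas real EEG noise is colored and includes artifacts.  Passing
the validation experiments therefore demonstrates the *correctness of the
algorithms* under their stated assumptions, not expected accuracy on any
real emotion dataset.  SNR is exposed as a knob (the amplitude scale of
real recordings is not modelled); noise is calibrated to a target sensor
SNR rather than an absolute variance so tests are scale-free.

## Numerical and design choices

* Tie-breaks: `which.max` resolves standardized-power and probability ties
  toward the lowest index; continuous Gibbs draws make ties measure-zero.
* Negative correlations: the Laplacian theory needs nonnegative weights,
  so edges use |r| by default; a signed mode exists behind a flag.
* β defaults to 0.3; thresholding that disconnects the graph warns but
  does not stop the classifier.
* Epoch windows are half-open `[start, start + len)` over 0-based samples;
  class balancing increases the minority class's overlap until counts
  match exactly.
* Splits: subject-dependent takes 40% of trials per subject (stratified by
  class, so ten trials give the 4-train/6-test pattern); subject-independent
  partitions subjects 40/40/20 into train/test/validation with a hard
  no-leakage assertion.
* Dataset containers, graph edge lists, reports and chain diagnostics are
  plain text (TSV/JSON); sensor epochs can also be exported to EDF.

## Problem sizes used in the validation experiments

The shipped experiments run at desk scale by design: Chebyshev/spectral
equivalence on 20 random graphs of up to 30 nodes; the one-coordinate
distributional check with 10⁵ draws; support recovery at N = 32, M = 200,
3 active sources, 20 dB over 20 seeds; sLORETA zero-localization over all
20 placements of an 8 × 20 toy plus 50 random placements at 32 × 200; the
full pipeline on the default 10 × 10 dataset in both split modes; and the
dynamic-vs-static adjacency comparison over 5 seeds on the
connectivity-discriminative set.  All are reproducible from a single seed,
e.g.:

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 1))
report
```

## Known limitations

* Scalar (fixed-orientation) dipoles only; no free-orientation triples and
  no 3 × 3 sLORETA standardization blocks.
* Single-measurement-vector prior: time samples are localized via
  snapshots, not a joint multi-sample prior.
* No convergence diagnostics beyond trace export; chains are short and the
  problems small by construction.
* Two classes by default; `n_classes` is configurable but the synthetic
  generator only produces binary labels.
* Connectivity features are Pearson correlations; coherence- or
  phase-based edges are deliberate future work.
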