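---
title: "Multi-channel complex dMRI denoising: models, parameters and design choices"
author: "mccdenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel complex dMRI denoising: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffusion MRI trades signal for resolution and diffusion contrast: at small
voxel sizes and high b-values the per-voxel signal drops below the thermal
noise. Worse, the usual magnitude images have Rician (single channel) or
noncentral-chi (multi-channel, root-sum-of-squares) statistics, so noise
does not average to zero — it accumulates into a positive *noise floor*
below which true signal is unmeasurable. Free water (CSF) at b = 3000
s/mm² has true attenuation exp(−9) ≈ 1.2·10⁻⁴: at any realistic SNR this is
orders of magnitude under the floor.

The data as acquired, however, are complex-valued and per-channel, and the
noise in them is additive Gaussian. This package denoises the
**multi-channel complex (MCC)** data *before* magnitude formation and
channel combination, where (i) the Gaussian noise model of random matrix
theory actually holds and (ii) the redundancy across spatial neighbors,
receiver channels and diffusion volumes is maximal.

## Block low-rank model

A local block of `k × k × k` voxels across `C` channels and `V` volumes is
reshaped into an `M × N` matrix `S` (`M ≤ N`, aspect ratio `δ = M/N`). The
underlying signal is low rank; thermal noise makes the matrix full rank.
Write the SVD `S = U Σ Vᵀ` and normalize the singular values by the noise
scale,

    y_i = s_i / (σ √N).

In these units the singular values of a pure-noise matrix asymptotically
fill the Marchenko–Pastur (MP) bulk `[1 − √δ, 1 + √δ]`; anything above the
bulk edge `1 + √δ` carries signal. Denoising replaces each `y_i` by `η(y_i)`
and reconstructs `σ √N · U diag(η) Vᵀ`. Seven spectrum policies are
provided:

| strategy | `η(y)` above its threshold | character |
|---|---|---|
| `mp_pca`  | `y` kept unchanged for the fitted signal count `P` | keep-or-kill, self-calibrating |
| `tsvd`    | `y` for `y ≥ 1 + √δ` | keep-or-kill at the bulk edge |
| `hard`    | `y` for `y ≥ y†(δ)` with `y† = √(2(δ+1) + 8δ/((δ+1) + √(δ²+14δ+1)))` | keep-or-kill, optimal location |
| `soft`    | `y − (1 + √δ)` | shrink by the edge |
| `fro`     | `√((y²−δ−1)² − 4δ)/y` | optimal for Frobenius loss |
| `op`      | `z(y)` | optimal for operator loss |
| `nuc`     | `(z⁴ − δ − √δ·y·z)/(z²y)` if `z⁴ ≥ δ + √δ·y·z`, else 0 | optimal for nuclear loss, most aggressive |

with the debiased singular value
`z(y) = √((y² − δ − 1 + √((y² − δ − 1)² − 4δ))/2)` for `y ≥ 1 + √δ` and 0
below. Pointwise `η_nuc ≤ η_fro ≤ η_op ≤ y` above the common threshold;
the suite checks this on a `(y, δ)` grid.

Numerical guards: `(y² − δ − 1)² − 4δ` is analytically non-negative above
the bulk edge but can round below zero; it is clamped at 0. The truncated
SVD tie-break retains a value exactly at the edge. Matrices with `M > N`
are transposed on ingestion so `δ ∈ (0, 1]` always.

## Noise estimation

Two estimators are implemented, both from the block's own spectrum:

* **MP-median** (default for all thresholding/shrinkage strategies):
  `σ̂ = s_med / √(N·μ_δ)`, where `s_med` is the median empirical singular
  value and `μ_δ` the median of the MP law at the block's aspect ratio
  (found by quadrature + root bracketing, tolerance 1e-8, cached per block
  geometry). Because a handful of signal spikes cannot move the spectral
  median, this estimator is robust in signal-bearing blocks.
* **Simultaneous MP fit** (used by MP-PCA itself and by the magnitude
  baseline): candidate noise bulks are grown from the smallest eigenvalue
  of `S Sᵀ` upward; a bulk is accepted while its MP width estimate
  `(λ_max − λ_min)/(4√γ)` stays below its mean; the largest accepted bulk
  gives `σ̂²` (the bulk mean of `λ/N` — the normalization that recovers σ
  on pure noise) and the signal count `P`.

MP-PCA retention: the `P` fitted components are kept unchanged, plus any
eigenvalue at or above the `(M−P)·σ̂²` variance threshold. The union makes
the degenerate noise-free branch lossless (an exactly low-rank block passes
through bit-for-bit) while preserving the small-matrix behavior that
motivates optimal shrinkage: at 20×20 the fit's bulk is so short that a
noise component is retained in a nonzero fraction of draws, and the
retained signal value is never debiased — both visible in the
planted-spike study (`planted_spike_study()`).

A deliberate consequence of per-block estimation: noise may vary across
space, and each block uses its own σ̂. The estimators assume the noise is
approximately constant *within* a block; see the phantom section for what
happens when it is not.

## Pipeline

`denoise_mcc()` chains:

1. **Channel decorrelation** — Mahalanobis whitening `S ← Φ^(−1/2) S` with
   the Hermitian inverse square root of the channel noise covariance `Φ`
   (estimated from background voxels via `estimate_channel_cov()`, or read
   from a file). Real and imaginary parts share `Φ`. Near-singular
   estimates are ridge-regularized by `1e-6 · trace(Φ)/C` (condition
   number > 1e8) — the conditioning policy is this package's choice.
2. **Two-pass phase unwinding** — the real and imaginary stacks are first
   denoised independently (same plan and, by design, the same strategy as
   the main pass — one code path, one configuration); the argument of the
   resulting complex estimate is the background phase (it absorbs the coil
   phase too), which is unwound per volume and channel. After unwinding the
   signal lives in the real part; the imaginary part is discarded.
3. **Block-wise recovery** — sliding `k³` blocks at stride `t`, each block
   denoised with the chosen strategy, per-block σ̂.
4. **Aggregation** — a voxel receives one estimate from every block
   containing it; they are combined with weights `w_j = 1/(1 + R_j)` where
   `R_j` is the block's retained rank, favoring smoother reconstructions
   and damping Gibbs ringing.
5. Optional **phase rewinding** and de-whitening.

Block geometry: `plan_blocks()` defaults to the smallest odd `k` with
`k³ ≥ C·V` (so `M = C·V ≤ N = k³`); a fixed kernel (5×5×5 in all studies
here, for comparability with magnitude-domain tools) is also supported.
Blocks are placed fully inside the volume — no padding, since padded
voxels would bias σ̂; at stride 1 every voxel is covered (interior voxels
by `k³` blocks). Strides above 1 are allowed with a blocking-artifact
warning, and uncovered voxels pass through unchanged.

Degenerate inputs: `C·V = 1` is refused (no redundancy); blocks with
σ̂ = 0 pass through unchanged; NaN input is an error.

The magnitude baseline `denoise_magnitude_baseline()` applies MP-PCA with
the simultaneous fit to 5×5×5 blocks of the channel-combined magnitude.
Its fitted σ̂ is corrected for the Rician bias of magnitude statistics by
the method-of-moments variance factor ξ(θ) (fixed point on
`σ_g = σ_mag/√ξ`); no correction can remove the floor bias already present
in the magnitude *mean*, which is exactly why the baseline cannot match
MCC denoising on the noise-floor metric.

## The digital phantom

`simulate_mcc()` draws from the acquisition model

    S̃_c(x,v) = R_c(x) · S(x,v) · exp(i φ_BG(x,v)) + ε_r + i ε_i,
    ε ~ N(0, σ(x)²) iid across voxel, channel, volume, re/im.

* **Compartments**: tube-shaped fiber bundles (straight, bending via a
  quadratic control point, fanning, kissing, crossing) with single-tensor
  attenuation `exp(−b(D⊥ + (D∥−D⊥)(g·u)²))`, `D∥ = 1.7e-3`,
  `D⊥ = 0.4e-3 mm²/s`; isotropic spheres with `D = 3.0e-3 mm²/s`
  (free water). Overlapping compartments mix with equal fractions.
* **Protocol**: b = 0/1000/2000/3000 s/mm² with 5/24/48/96 volumes
  (V = 173); deterministic Fibonacci-sphere directions per shell.
* **Sensitivity maps**: one Gaussian lobe per coil arranged around the
  FOV with a smooth linear phase; the array is normalized so Σ|R_c|² = 1
  at the FOV center. For channel-count sweeps, `coil_array` fixes the
  virtual array size and `channels` sub-samples it — each retained coil
  keeps its sensitivity, so the collected signal scales with the channel
  count, as it does when sub-sampling a physical array. (Normalizing
  every subset to unit center energy instead would make the combination
  averaging gain independent of C and erase the redundancy benefit.)
* **Background phase**: `A·sin(2πf_x x/FOV + ψ_z)·sin(2πf_y y/FOV + χ_z)`
  with independent shifts per slice — smooth in-plane, abrupt across
  slices. Defaults `A = π/2`, `f_x = f_y = 1.5` cycles/FOV. The shifts are
  static across volumes by default: background phase is a property of coil
  geometry and slowly varying physiology. A `per_volume = TRUE` variant
  redraws them each volume; note that fully dynamic shifts make the real
  and imaginary stacks effectively full rank (every slice-volume pair is
  an independent pattern), which removes the redundancy that *any*
  denoising-based phase estimation relies on — the two-pass scheme then
  degrades by construction, not by implementation.
* **Noise map**: SNR (defined as the channel-free b = 0 signal over σ)
  rises monotonically from 2 at the center to 15 at the periphery. The
  radial profile is *plateaued* (constant inside 0.55 of the maximal
  radius and outside 0.8 of it, cosine ramp between) rather than strictly
  linear. The reason is a scale artifact: on a ≤ 24³ desk grid a linear
  2→15 ramp changes σ by a factor ≈ 2.6 *inside a single 5³ block*, a
  strongly non-stationary regime that a full-size FOV (where one block
  spans a few percent of the radius) never enters; the local MP bulk then
  widens into a variance mixture and the simultaneous fit retains nearly
  everything. The plateaus restore the locally-stationary regime the
  estimators are built for, while keeping the prescribed center-worst SNR
  span. The free-water probe sits at the grid center, inside the
  worst-SNR plateau.
* **Reproducibility**: one root seed; noise, phase shifts and map jitter
  use deterministically derived sub-seeds; identical configuration and
  seed give bit-identical output.

What the phantom does **not** emulate: EPI/k-space artifacts (ghosting,
partial Fourier), gradient nonlinearity, motion, multi-band aliasing,
realistic electrodynamic coil maps, or anatomical geometry. Passing the
in-silico suite therefore shows that the estimator chain behaves as the
theory predicts under its stated noise model — not that artifact-laden
in-vivo data will denoise equally well.

## Validation studies and problem sizes

The package's studies are sized for a single CPU:

* `noise_floor_study()`: mini phantom, 16³ grid, C = 32, V = 173,
  5×5×5 kernel, stride 1 (1728 blocks of 125 × 5536). All seven MCC
  strategies share each block's eigendecomposition in one sweep. The
  free-water floor at b = 3000 is measured over the CSF-like sphere
  before/after denoising; the phase-enabled arm runs the full
  two-pass-unwinding pipeline with nuclear-norm shrinkage.
* `channel_sweep_study()`: same phantom at C ∈ {1, 2, 4, 8} sub-sampled
  from a 32-coil array, fixed V = 173, paired seeds; error is the
  mean-normalized difference to the noise-free ground truth inside the
  fiber mask. The fiber mask is the analogue of evaluating within a
  tissue contour: free-water voxels at high b have essentially zero true
  signal, so their normalized error is noise-floor-limited by
  construction and would drown the redundancy trend.
* `planted_spike_study()`: square rank-1 matrices (20, 50, 100) with the
  spike at 5× the pure-noise bulk edge, 100 seeded draws.

On the sum-of-squares-combined mini phantom the measured floor-reduction
folds are far larger than at full scale (hundreds rather than ~10×),
for two compounding reasons: the sos floor over 32 channels is ≈ σ√(2C)
(≈ 8σ) while the centrally placed free-water blocks are *pure* noise at
locally constant σ and are therefore almost completely annihilated by the
shrinkers. The studies accordingly check the reductions as lower bounds.

Division guard in the normalized error: entries with truth below
`1e-6 ×` its maximum are excluded (and counted), since division by the
truth is undefined there.

## Known limitations

* Phase estimation needs per-channel data SNR of roughly 5 upwards to
  reach ~0.1 rad accuracy; at per-channel SNR well below 1 (high channel
  counts with unit-normalized maps) the weak signal components fall below
  the detection edge and the estimated phase in low-signal voxels is
  uninformative — harmless for noise-floor suppression, relevant if the
  rewound phase is consumed downstream.
* MCC processing is memory-hungry: the mini phantom is ~360 MB as a
  complex array and each strategy's output adds ~180 MB; the studies
  free intermediates eagerly and compute derived maps strategy by
  strategy.
* The residual-shape check (skewness/kurtosis of the normalized
  residual) is only meaningful under locally homogeneous noise: mixing
  residual variances inflates kurtosis even for perfectly noise-like
  residuals.
* SENSE/GRAPPA reconstruction, motion/distortion correction and
  downstream model fitting are out of scope; channel combination is
  root-sum-of-squares or sensitivity-weighted.
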