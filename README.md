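# mccdenoise

Noise-floor suppression for diffusion MRI by denoising **multi-channel
complex (MCC)** data — the per-coil complex images before magnitude
formation — with sliding-block low-rank matrix recovery and optimal
singular-value shrinkage.

## Why

Magnitude dMRI data have Rician / noncentral-χ statistics: noise does not
average to zero but accumulates into a positive *noise floor*. At high
diffusion weighting, fast-decaying signals (free water at b = 3000 s/mm²
decays to exp(−9) ≈ 10⁻⁴ of its b = 0 value) vanish under that floor, and
no amount of magnitude-domain denoising can recover them, because the bias
sits in the magnitude *mean*. The complex per-channel data, in contrast,
carry additive Gaussian noise — the regime in which random-matrix theory
makes signal/noise separation in a local signal matrix well-posed — and
offer far more redundancy (spatial neighbors × channels × volumes).

## What it does

A local `k×k×k` block across `C` channels and `V` volumes is reshaped into
an `M×N` matrix `S` (`M ≤ N`, `δ = M/N`). With singular values normalized
as `y = s/(σ√N)`, pure noise fills the Marchenko–Pastur bulk
`[1−√δ, 1+√δ]`; each strategy maps `y ↦ η(y)`:

* **MP-PCA** — keep the `P` components found by a simultaneous MP fit,
  unchanged;
* **TSVD** / **Hard** / **Soft** — keep-or-kill at the bulk edge, at the
  optimal hard-threshold location `y†(δ)`, or shrink by the edge;
* **Fro / Op / Nuc** — optimal shrinkage under the Frobenius, operator and
  nuclear norms, built on the debiased transform
  `z(y) = √((y²−δ−1+√((y²−δ−1)²−4δ))/2)`.

The full pipeline (`denoise_mcc()`): channel decorrelation by Mahalanobis
whitening of the coil noise covariance → two-pass background-phase
unwinding (denoise real/imaginary parts, take the argument, unwind) →
block-wise recovery on the real part with per-block noise estimation
(MP-median or simultaneous MP fit) → rank-weighted aggregation of
overlapping blocks (`w = 1/(1+rank)`) → optional phase rewinding and
channel combination (root-sum-of-squares or sensitivity-weighted).

The package also ships the in-silico study apparatus: a parametric
multi-compartment digital phantom (fiber bundles with
`D∥ = 1.7·10⁻³ mm²/s`, `D⊥ = 0.4·10⁻³ mm²/s`, free-water spheres with
`D = 3.0·10⁻³ mm²/s`, 173-volume b = 0/1000/2000/3000 protocol, coil
sensitivity maps, sinusoidal background phase, spatially varying noise
with SNR 2–15), evaluation metrics (mean-normalized error, per-shell
PSNR, noise-floor measurement, residual shape statistics, tractography
score), and a planted-spike toy for contrasting shrinkage strategies.

## Worked example

```r
library(mccdenoise)

## 1. a rank-1 matrix buried in noise: nuclear-norm optimal shrinkage
ps  <- planted_spike_matrix(size = 50, spike = 5 * 2 * sqrt(50),
                            sigma = 1, seed = 1)
den <- denoise_matrix(ps$noisy, strategy = "nuc")

## 2. the multi-channel phantom, end to end
cfg <- default_phantom("mini", channels = 8, seed = 42)
sim <- simulate_mcc(cfg)
d    <- dim(sim$image$data)
plan <- plan_blocks(d[4], d[5], d[1:3], mode = "fixed", k = 5)
res  <- denoise_mcc(sim$image, strategy = "nuc", plan = plan)

noisy_sos <- combine_channels(sim$image, "sos")
den_sos   <- combine_channels(res$image, "sos")
floor_ratio(noisy_sos, den_sos, sim$truth$csf, sim$image$bvals)
```

prints

```
retained rank: 1 (true rank 1)
estimated sigma: 1.028 (true 1)
Frobenius error, noisy:    51.8
Frobenius error, denoised: 10.5
free-water floor at b = 3000, noisy:    1.9759
free-water floor at b = 3000, denoised: 0.131877
fold reduction: 15
```

Reading this: the shrinker identified exactly the one signal component and
cut the matrix error five-fold; on the phantom, the mean free-water signal
at the highest b-value — pure noise floor, since the true signal there is
≈ 10⁻⁴ — drops 15-fold after denoising, pulling the measured decay curve
back onto the exponential it should follow.

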