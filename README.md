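# denoise4d

True 4D adaptive image denoising for time-resolved volume data — (x, y, z, t)
scalar fields such as gated cardiac CT, where low per-timepoint dose makes the
images noisy but the temporal periodicity and spatial smoothness of anatomy
leave a lot of recoverable signal in the 4D neighbourhood of every voxel.

The package is written for image-analysis researchers and engineers who want a
tested, desk-scale reference implementation of structure-tensor steered
filtering in two to four dimensions: the filter banks, the tensor machinery and
the out-of-core bookkeeping, with both an exact-frequency-response backend and
a compact windowed-kernel backend.

## The method

Adaptive filtering is a direct (non-iterative) two-stage scheme:

1. **Estimate the local structure tensor.** A bank of 14 monomial filters —
   4 odd first-order (frequency responses −i R(ρ) ûₘ) and 10 even second-order
   (R(ρ) ûₘûₙ) with a lognormal radial profile R (centre frequency u₀ = 3π/5,
   bandwidth 2.5 octaves) — yields response fields fr₁…fr₁₄, combined per voxel
   as T = Q₁Q₁ᵀ + Q₂Q₂ᵀ into the symmetric 4×4 tensor. Squaring odd and even
   responses makes T phase invariant (edges and lines of either polarity give
   the same tensor).
2. **Map and reconstruct.** Because 4×4 matrices have no closed-form
   eigensolver, the tensor is mapped without eigendecomposition:
   magnitude T_mag = ‖T⁸‖_F^{1/8} (three matrix squarings; within 9% of λ₁),
   normalized to γ₀ ∈ [0, 1] over the dataset and passed through the
   M-function γ = γ₀^β / (γ₀^{α+β} + σ^β); shape via the matrix polynomial
   C = γ (I − (I − T̂_f)⁸(I + 8T̂_f)), T̂_f = T̂²(I + 2(I − T̂)), which maps each
   eigenvalue through an S-shaped transfer with fixed points 0 and 1. The
   output is i_d = i_lp + Σₖ wₖ Cₖ i_hp(k): an isotropic lowpass plus ten
   directional highpass responses weighted by the control tensor, so smoothing
   follows oriented structure but never crosses it.

Tensor estimation runs at half resolution (lowpass + downsample by 2 in
x, y, z), the control tensor is interpolated back on the fly, and the z-axis
can be processed in slabs with exact overlap margins for out-of-core datasets.

## Worked example

Denoise the classic step/line/shading phantom (127×127×9×9, signal constant
over z and t, heavy additive noise):

```r
library(denoise4d)

ph  <- make_fig1_phantom(noise_sigma = 0.4, seed = 1)
cfg <- pipeline_config(backend = "fft", sigma = 0.5)  # sigma tracks the data SNR
den <- denoise_4d(ph$noisy, cfg)

sprintf("input SNR:  %.2f dB", snr_db(ph$clean, ph$noisy))
#> "input SNR:  -7.52 dB"
sprintf("output SNR: %.2f dB", snr_db(ph$clean, den$values))
#> "output SNR: 5.14 dB"
```

A +12.7 dB improvement: the noise std is cut by a factor ~4 while the step,
the one-pixel line and the shading ramp survive. Restricting the same
pipeline to one slice (2D) or one volume (3D) shows the power of
dimensionality — `fig1_dimensionality_experiment(seeds = 1:5)` reports output
SNRs ordered strictly 2D < 3D < 4D on every seed (−1.9 / +2.1 / +5.1 dB for
seed 1), because every added, signal-constant dimension averages away more
noise.

The out-of-core planners reproduce the production bookkeeping:

```r
plan_valid_slices(51, use_normalized_conv = TRUE)[c("after_downsample",
                                                    "after_monomial",
                                                    "final_output")]
#> $after_downsample  26      # 51 slices downsample to 26
#> $after_monomial    20      # control tensor on 20 half-res slices
#> $final_output      39      # 39 denoised full-res slices per run

nrow(plan_slabs(445, slab_size = 51))
#> 12                         # runs to denoise a 445-slice dataset

count_multiplications(c(512, 512, 445, 20), 11, 11)
#> 3.757451e+14               # direct spatial reconstruction cost
storage_bytes(c(512, 512, 445, 20), 11) / 1e9
#> 102.6556                   # GB of float32 filter responses
```

A thin command-line wrapper is installed with the package
(`system.file("cli", "denoise4d", package = "denoise4d")`) with subcommands
`run`, `plan`, `cost` and `phantom`; volumes travel as NIfTI-1 or raw float
with a JSON sidecar.

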