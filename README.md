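# gridpcxi

Single-grid phase-contrast X-ray imaging in R: extract a phase-contrast
image from **one** raw carrier-modulated detector frame via the
instantaneous frequency of the analytic signal, then clean it with a
two-step noise filter (adaptive Gaussian notch + bitonic filters). The
conventional Fourier-analysis demodulation (absorption, scattering and
differential-phase images from grid / sample+grid frame pairs) is included
for comparison, together with a synthetic grid-phantom simulator so every
stage is testable without detector data.

## Who this is for

Researchers working on grating- or grid-based phase-contrast imaging who
want a self-contained, seeded reference implementation of

* single-frame phase retrieval by instantaneous frequency,
* harmonic-ratio demodulation of carrier-modulated frames,
* adaptive spectral notch filtering of periodic (Moire-like) artefacts,
* simple / structurally varying / multi-resolution structurally varying
  bitonic denoising,
* PSNR / MSE / SSIM image quality evaluation.

## The method

A one-dimensional absorption grid (pitch `p = 0.118` mm) placed between
source and detector projects a vertical line pattern, magnified by the
geometry to a carrier of period `p (SDD/SGD) / s ≈ 34.87` pixels
(`s = 7` µm pixels, SGD = 700 mm, SDD = 1448 mm). The sample modulates
this carrier: transmittance `T` scales the envelope, small-angle scattering
reduces the modulation visibility `V`, and differential phase shifts the
carrier locally by `φ_s`:

```
I(x, y) = B · T(x, y) · [1 + V(x, y) · cos(2π f₀ x + φ_s(x, y))]
```

**Instantaneous-frequency retrieval** works row by row on a single frame:

1. analytic signal `z(x) = row(x) + i · HT(row(x))` (Hilbert transform),
2. wrapped phase `φ(x) = arg z(x)`, unwrapped by adding ±2π wherever a
   consecutive difference exceeds π,
3. instantaneous frequency `Insfre(x) = fs/(2π) · dφ/dx`, with `fs` the
   row length (units: cycles per line).

Deviations of `Insfre` from the carrier frequency are proportional to
`∂φ_s/∂x` — the phase-contrast image.

**Two-step filtering.** Step 1 segments periodic-noise peaks in the
amplitude spectrum (adaptive local-median threshold, region growing) and
suppresses each with an inverted Gaussian notch, leaving DC and a protect
list untouched. Step 2 applies the multi-resolution structurally varying
bitonic filter: rank-based robust opening/closing over structure-adaptive
elliptical masks, a robustly weighted Gaussian smoothing of the residual,
and a pyramid recursion for coarse-scale noise.

**Fourier demodulation** (the conventional route) windows the spectrum
around DC and around the carrier peak for both grid-only and sample+grid
frames, then forms `Abs = |SG₀ₕ|/|G₀ₕ|`,
`Scatt–PCXI = (SG₁ₕ/G₁ₕ)·(G₀ₕ/SG₀ₕ)`, `Scatt = |Scatt–PCXI|`,
`PCXI = atan2(Im, Re)`.

## Worked example

```r
library(gridpcxi)

acquisition_geometry()
#> Single-grid acquisition geometry
#>   grid pitch      : 0.118 mm
#>   pixel size      : 7 um
#>   source-grid     : 700 mm
#>   source-detector : 1448 mm
#>   detector        : 512 x 512 px
#>   carrier period  : 34.870 px (f0 = 0.02868 cycles/px)

res <- run_pipeline(pipeline_config(size = c(256, 256), seed = 7))
res
#> pcxi_pipeline result
#>   frame: 256 x 256, seed 7
#>  reference_id comparison_id  psnr_db          mse      ssim
#>      if_clean if_unfiltered 25.59142 0.0027596737 0.6500471
#>      if_clean   if_filtered 32.63155 0.0005455626 0.9833109
```

The pipeline simulates a fish-like phantom with the default noise profile
(a near-carrier Moire beat, Gaussian detector noise, salt-and-pepper
corruption), extracts the IF image, filters it in two steps, and scores
both the unfiltered and filtered images against the noise-free ground
truth: here the two-step filter lifts SSIM from 0.650 to 0.983 and PSNR
by ~7 dB. Everything is bit-reproducible under the seed.

A thin CLI over the same functions lives in `inst/cli/gridpcxi`
(subcommands `simulate`, `fourier`, `insfreq`, `notch`, `bitonic`, `run`).

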