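---
title: "Single-grid phase-contrast imaging by instantaneous frequency: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-grid phase-contrast imaging by instantaneous frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpcxi)
```

# The imaging model

A single absorption grid of pitch 0.118 mm, placed 700 mm from the
source with the detector at 1448 mm, projects a vertical line pattern
magnified onto 7 µm pixels, giving a horizontal carrier of period

```{r}
carrier_period_px(acquisition_geometry())
```

pixels. The simulator's forward model treats the sample as three
per-pixel fields acting on this carrier:

$$I(x,y) = B\,T(x,y)\,\bigl[1 + V(x,y)\cos(2\pi f_0 x + \varphi_s(x,y))\bigr]$$

with transmittance $T\in(0,1]$, visibility $V\in[0,1]$ (reduced by
small-angle scattering), and a differential-phase carrier shift
$\varphi_s$ in radians. This multiplicative form is chosen because it
makes the harmonic-ratio demodulation an exact inverse on noise-free
data: the zeroth harmonic carries $B\,T$, the first harmonic
$\tfrac12 B\,T\,V e^{i\varphi_s}$. Noise enters as additive sinusoids
(Moire-like beats), additive white Gaussian noise, and finally
salt-and-pepper replacement. Grid lines are vertical and `x` is the
column index, because the retrieval operates on rows.

What the simulator deliberately does **not** emulate: polychromatic
spectra, detector point-spread, Talbot self-imaging, cone-beam
magnification of the sample, or geometric ray bending — differential
phase enters only as the local carrier shift. Tests passing on this
phantom therefore validate the *signal-processing chain*, not the
physics of any particular beamline; real frames add PSF blur,
polychromatic visibility loss and structured detector noise that the
phantom does not represent.

## The fish-like phantom

`make_fish_like_phantom()` builds a seeded scene with one soft-tissue
body ellipse (15% attenuation, *constant* phase plateau of 0.4 rad in
its interior) crossed by thin rib ellipses (45% attenuation, phase
following a *quadratic arc* of 0.3 rad across each rib). The two
pixel-profile signatures — flat over soft tissue, parabolic over bone —
are the discriminating feature the phase image is expected to show.
Ribs are confined to the lower body so rows in the upper body cross
soft tissue only; landmark coordinates ride along as an attribute for
profile-based tests.

Two calibrations are physical constraints, not free dials:

* **Pull-in condition.** The analytic-signal phase can only track
  $\varphi_s$ while $|\partial\varphi_s/\partial x| < 2\pi f_0$ (the
  local frequency must never stall or reverse). The rib arc height
  (0.3 rad) over the rib half-width (1.8% of the image width) keeps the
  peak phase slope at ~70% of the carrier increment. Steeper arcs make
  the analytic amplitude collapse and the phase glitch — visible as
  spike artefacts at bone edges, which real IF images of bone also
  show.
* **Finite edge width.** Structure edges are tanh-tapered over a few
  pixels. Sub-pixel hard edges are unphysical for a system whose
  100 µm focal spot alone projects a multi-pixel penumbra at this
  magnification.

# Instantaneous-frequency retrieval

Per row: mean removal, Hilbert transform via the DFT (negative
frequencies zeroed, positive doubled, DC and Nyquist kept at unit
weight), wrapped phase, unwrapping, then
$\mathrm{Insfre}(x) = \frac{f_s}{2\pi}\frac{d\varphi}{dx}$ with $f_s$
equal to the row length, so units are cycles per line.

Decisions worth recording:

* **Mean removal** before the Hilbert transform: a DC offset biases the
  analytic phase; grid rows ride on a large base intensity, so the
  offset is removed per row even though the defining equation uses the
  raw row.
* **Unwrapping** is implemented exactly as the published scan — each
  jump larger than π shifts the entire remaining tail by ±2π, one turn
  at a time. This makes the implementation bit-identical to a literal
  transcription of the pseudocode, which the test suite exploits
  (10^5 random sequences compared with `identical()`).
* **Gradient scheme**: central differences with one-sided edge columns
  (a forward-difference mode is available). With this scheme the
  trapezoid-rule row integral of the IF image telescopes exactly to
  $\varphi(N) - \varphi(1)$, asserted to 10⁻⁹ in the tests.
* **No row apodization** is applied before the Hilbert transform. The
  carrier does not complete an integer number of cycles per row, so
  spectral leakage produces a low-amplitude IF ripple across the row
  (standard deviation ≈ 0.2 cycles/line at 256² with this geometry)
  and larger excursions in the outermost columns, which are the
  documented low-trust zone. Consequences for testing: the
  IF-tracks-phase-gradient property (correlation > 0.95) is asserted on
  a full-support smooth phase field, where the tracking term dominates
  the ripple; on sparse phantoms the global correlation is diluted by
  ripple over the empty background, which is a property of the method,
  not a bug.
* **Display normalisation** (min–max to [0, 1]) happens only at write
  time; the pipeline carries physical units throughout.

# Fourier demodulation

The spectrum is windowed with raised-cosine (Tukey, taper 0.5) disks
around DC and around the +carrier peak; the first harmonic is shifted
to baseband by multiplication with $e^{-2\pi i(f_x x + f_y y)}$ at the
(sub-bin) carrier frequency, so its angle is the local carrier phase.
Only the + conjugate peak is used — for real images the − peak is
redundant. The absorption image is the ratio of zeroth-harmonic
*moduli*; the complex ratio keeps its angle for the phase image,
mapped to the principal value (−π, π].

The default window radius is 0.4·|carrier|. The radius is a genuine
trade-off: the band-limited point-spread has main-lobe width
≈ 1/radius, and its sidelobes ripple through hard-edged objects. On
the 512² hard-edged disk phantom the 0.4 band leaves ~2.6% median
interior ripple while the maximal non-overlapping band (0.5·|carrier|)
reaches ~1.7%; the parameter-recovery tests therefore use 0.5 while
0.4 remains the package default for general use (less ringing
amplification of near-band noise). Division safety: divisor moduli
below 10⁻⁶ of the grid zeroth-harmonic maximum flag the pixel invalid
(output 0, mask exposed) rather than raising an error.

Carrier location applies a Hann window before the FFT so the parabolic
sub-bin refinement of the log-amplitude peak is nearly unbiased; the
located period on simulated frames is within 0.1% of the geometric
value.

# Adaptive Gaussian notch (step 1)

The log-amplitude spectrum is thresholded at local median +
`k_sigma` × 1.4826·MAD over a sliding 31×31-bin window (`k_sigma` = 4),
seeds grow 8-connected down to threshold − 1 log-unit, conjugate
regions are paired, and each region is suppressed by an inverted
Gaussian bump (σ = 1.5 × equivalent radius, depth 1). The mask is
symmetric under frequency negation (realness), identically 1 inside a
DC guard disk (default 3 bins — the mean is preserved exactly; the
output is re-anchored to the input mean to absorb ~10⁻¹³ FFT
round-off), and never touches protected disks (the carrier, when the
module is used on raw frames or IF images with known geometry).

One rule was added beyond the published description: a **compactness
cap** (default equivalent radius ≤ 5 bins). Periodic noise is
spectrally narrow; broad supra-threshold blobs are sample texture
(e.g. the quasi-periodic rib comb of the phantom produces a broad
structure peak that the threshold alone cannot distinguish from
noise). Without the cap, step 1 notches anatomy and measurably erodes
edge energy; with it, a noise-free IF image passes through unchanged
to 10⁻⁶ RMS while injected tones are still suppressed by ≥ 95%. The
window size, threshold constant, margin, spread factor, guard radius
and cap are all exposed parameters.

# Bitonic filters (step 2)

All three variants share the two-stage structure: a rank-based
morphological stage and a linear residual stage.

* **Rank morphology.** Robust opening = rank-dilation(rank-erosion),
  robust closing = rank-erosion(rank-dilation), with erosion/dilation
  the `centile` / `100 − centile` percentiles (default 10%; 50 is a
  median). The stage's intermediate is the average of opening and
  closing. The rank (rather than min/max) form is what removes
  impulses: a true closing preserves a salt spike exactly, a 10th-
  percentile one rejects it.
* **Residual stage.** The residual (image − intermediate) is smoothed
  with a Gaussian (σ = 0.33 × parameter) and added back, so detail the
  morphology kept is untouched. The smoothing is a *robustly weighted*
  normalised convolution (Cauchy weights, scale 3 × MAD): a plain
  convolution re-injects ~3% of every impulse (the kernel's central
  weight), which alone caps salt-and-pepper restoration near 88%;
  down-weighting gross residuals removes that path while leaving
  noise-scale residuals smoothed essentially linearly. `robust_k = Inf`
  recovers the plain scheme.
* **Structure-adaptive masks** (structvar variants). Per pixel, a
  local matrix built from smoothed outer products of first differences,
  augmented on the diagonal with smoothed squared second differences —
  the second-order terms supply orientation exactly where first
  derivatives vanish (ridge and valley centrelines). The stored
  orientation is the leading-eigenvector (gradient) angle; the
  rasterised elliptical footprint is elongated *perpendicular* to it,
  i.e. along the structure, with axis ratio √(λ₁/λ₂) clipped at
  `anisotropy_max` (default 4). The tensor is estimated on a
  3×3-median-prefiltered copy (the data path is untouched): without
  this, impulse noise inflates the tensor isotropically, masks
  degenerate to discs, and thin dark valleys get filled.
* **Multi-resolution recursion.** Filter at the current level, reduce
  by 2 (5-tap binomial anti-alias), recurse, enlarge, and recombine as
  `I_F + enlarge(LLC − I_FR)`. The literal recombination was found to
  inject coarse-level erosion of structures that are under-resolved
  after reduction (thin ribs are a few pixels at level 3 and are eaten
  by masks that cannot shrink below the centre pixel), so the
  upsampled correction is soft-clipped with the same Cauchy/MAD
  weighting as the residual stage: broad low-amplitude noise
  corrections pass unchanged, gross localised ones do not. With this,
  restoration quality is independent of pyramid depth and the
  selection ordering (multires(7) > structvar(7) > simple(7)/simple(9)
  in SSIM on the standard noisy fixture) emerges. Default depth is
  `log2(min dimension) − 4`, stopping below 16 px.
* **Boundaries**: mirror padding (no edge repeat) everywhere, for the
  rank kernels, the convolutions and the pyramid.

The centile, σ-factor, anisotropy bound and depth defaults are
reconstruction choices validated by the property suite, not published
facts.

# Metrics and fixtures

MSE, PSNR (`10·log10(1/mse)`, peak 1) and SSIM (Gaussian 11×11 window,
σ 1.5, stabilisers (0.01)², (0.03)², L = 1 — the standard constants,
adopted because none are published for this workflow) operate on
images min–max scaled to [0, 1] over the reference image's range.
PSNR of identical images is reported as `Inf`. Note that an MSE of
0.0019 on the unit scale corresponds to 27.21 dB under this
definition; the package never mixes peak conventions.

The denoising criteria use the *scene* image (base intensity ×
transmittance of the fish phantom) as the piecewise-smooth ground
truth. The carrier-modulated raw frame is not a meaningful restoration
target (the filter is not supposed to preserve a 35-px sinusoid
texture), and the noise-free IF image itself oscillates by 5–15% from
spectral leakage, so a 5%-relative restoration bound is unattainable
on it for any filter; the scene is exactly the piecewise-smooth image
class the bitonic family is designed for, and is what the (carrier-
free) IF image approximates.

# Problem sizes and determinism

The test suite and the acceptance script run phantoms at 256² (512²
for the demodulation recovery, 64² for the white-noise trials), sizes
at which every stage's behaviour is fully developed — the carrier
period, filter footprints and pyramid depth all fit with an order of
magnitude to spare — while a full run stays in the low minutes on one
core. The full 3840 × 3072 detector format is supported but not
exercised by default. Every random draw is seeded (the simulator keeps
independent streams per frame kind, restoring the caller's RNG state),
and the pipeline is bit-reproducible: identical configurations produce
identical artifact files.

# Known limitations

* Edge columns of IF images are untrustworthy (no apodization; one-
  sided gradients).
* Differential phase beyond the pull-in slope produces spike
  artefacts, not graceful degradation.
* The notch compactness cap means genuinely broad-band periodic noise
  (strongly non-stationary Moire) is left to step 2.
* 2-D phase unwrapping, column-direction IF, crossed gratings and CT
  reconstruction are out of scope.
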