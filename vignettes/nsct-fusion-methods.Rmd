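---
title: "Methods: NSCT-domain multimodal image fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NSCT-domain multimodal image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsctfusion)
```

This vignette documents the models, parameter choices and numerical
conventions behind `nsctfusion`, in the order the pipeline runs them:
transform, activity measures, fusion rules, metrics, and the synthetic test
bed.

## The nonsubsampled contourlet transform

The NSCT decomposes an image into one low-frequency subimage and, per
pyramid level `k`, `2^l_k` directional high-frequency subimages. Both
stages are *undecimated*: signals are never resampled; instead the filters
are upsampled à trous (zeros inserted, i.e. their frequency responses are
evaluated at `2^j ω`) as the cascade deepens. Consequently every subband
has the input's size, the transform is linear, and — because all filtering
here is circular convolution implemented in the FFT domain — decomposition
commutes *exactly* with cyclic shifts. That shift invariance is the reason
to prefer the NSCT for fusion: selection rules applied to shift-dependent
coefficients produce pseudo-Gibbs artifacts at selection boundaries.

**Pyramid stage.** A two-channel filter bank must satisfy
`H0·G0 + H1·G1 = 1` on the frequency plane to reconstruct perfectly without
decimation. The default realization (`pyramidFilter = "9-7"`) uses the
separable CDF 9/7 lowpass pair normalised to unit DC gain for
(analysis `H0`, synthesis `G0`) and closes the identity structurally:
`H1 = 1 − H0·G0` with identity highpass synthesis (`G1 = 1`) — the
nonsubsampled Laplacian-pyramid construction. Perfect reconstruction is
then exact by algebra, not by filter-coefficient coincidence, and the
highpass channel annihilates constants because `H0·G0` has unit DC gain. A
5-tap Burt–Adelson pair (`"burt"`) is provided as a second configuration;
the fusion rules are agnostic to the filter family, and the binding
contracts are perfect reconstruction, same-size subbands and shift
covariance, all of which the test suite enforces at 1e-6.

**Directional stage.** Each bandpass band is split by `2^l` smooth fan
windows on the frequency plane: wedges of width `π/2^l` on the orientation
axis (angles taken modulo π so the windows are symmetric under frequency
negation and subbands stay real), with raised-cosine crossfades whose
squared-cosine tapers are complementary between neighbours. The windows
therefore form an exact partition of unity, and with identity synthesis the
directional channels of any signal sum back to that signal. This is the
frequency-domain realization of the nonsubsampled directional filter bank;
ladder-structure spatial fan filters would be an equivalent alternative,
but the windowed construction makes perfect reconstruction and shift
covariance structural rather than numerical.

**Defaults.** `levels = 3` with direction exponents `c(2, 3, 4)` (coarse to
fine): three scales are standard for 256×256 inputs, and giving the finest
scale the most directions matches how oriented detail concentrates at high
frequency. Images must be at least `2^levels` pixels per axis; the pipeline
is float64 throughout, with clipping to [0, 255] and 8-bit rounding only at
file-write time.

## Log-Gabor energy: the high-frequency activity measure

A Log-Gabor filter is Gaussian on the log-frequency axis,

$$g(f,\theta) = \exp\!\left(-\frac{\ln^2(f/f_0)}{2\ln^2(\sigma/f_0)}\right)
               \exp\!\left(-\frac{(\theta-\theta_0)^2}{2\sigma_\theta^2}\right),$$

has no DC response by construction, and is applied here with a *one-sided*
angular window so each filtered subband is a complex quadrature pair; the
energy `E = Σ_{u,v} Re(G)² + Im(G)²` summed over the `U×V` bank is thus a
phase-insensitive local-spectrum measure. Averaging `E` over a
`(2M+1)(2N+1)` window gives the local energy `LE` that drives
high-frequency selection: unlike the per-pixel absolute-coefficient rule,
`LE` measures a neighbourhood, so isolated noise spikes do not capture
fused coefficients.

Bank defaults (all exposed in `logGaborParams()`): `U = 4` scales,
`V = 6` orientations, finest centre frequency `f0 = 1/3` cycles/pixel,
scale multiplier 2.1, `σ/f0 = 0.55` (≈ two-octave radial bandwidth),
`σ_θ = 0.52` rad. These are conventional Log-Gabor settings; the method
does not prescribe them, and one fixed bank is applied to every subband
rather than re-tuning per scale/direction — the subbands are already
band-limited, so per-subband re-tuning would mostly re-weight a measure
used only for a per-pixel *comparison* between the two sources.

The window default is `M = N = 1` (3×3): the smallest neighbourhood that
gives pixel context without blurring the selection map. The window's border
policy defaults to periodic rather than reflective padding: the rest of the
pipeline is circular, and a periodic window keeps the *fused output* — not
just the transform — exactly shift covariant, which we consider part of the
method's contract (reflective padding is available via
`energyBoundary = "reflect"`).

## Phase congruency: the low-frequency selector

Low-frequency subimages carry the approximation content; averaging them
(the common baseline) halves contrast wherever the modalities disagree,
which is precisely the interesting case in multimodal data. Instead, the
coefficient whose source shows stronger *phase congruency* is selected.
PC at a pixel is, per orientation,

$$PC^\theta = \frac{\sum_n W^\theta\left[A_n^\theta\left(\cos(\phi_n^\theta-\bar\phi^\theta) - |\sin(\phi_n^\theta-\bar\phi^\theta)|\right) - T\right]_+}{\sum_n A_n^\theta + \varepsilon},$$

with `A_n, φ_n` the amplitude and phase of Log-Gabor quadrature responses
at scale `n`, `φ̄` the amplitude-weighted mean phase, `W` a sigmoid weight
on the spread of response across scales, `T` a noise floor and `[·]_+`
half-wave rectification. Because numerator and denominator scale together,
PC is invariant to affine intensity rescaling — the property that makes it
meaningful to compare PC maps *across modalities* with different pixel
mappings.

Choices the formula leaves open, and what this package does:

- **Orientation aggregation**: numerators and denominators are summed over
  orientations before dividing, giving one scalar map per image bounded in
  [0, 1]. (Taking a per-orientation maximum instead would favour single
  oriented structures over corners; the summed form is the standard
  energy-weighted aggregate.)
- **Noise floor `T`**: estimated per orientation from the median
  finest-scale amplitude under a Rayleigh response model,
  `τ = median(A_1)/√(ln 4)`, propagated through the scale geometric series
  and set to `mean + k·σ` of the implied noise-energy distribution with
  `k = noiseThresholdK = 2`. The estimator is intensity-linear, so it does
  not break the invariance above.
- **Spread weight `W`**: sigmoid `1/(1 + exp(gain·(cutoff − s)))` with
  `s` the scale-normalised amplitude sum, `cutoff = 0.5`, `gain = 10`.
- **Defaults**: 4 scales, 6 orientations, finest wavelength 3 px,
  multiplier 2.1, `ε = 1e-4`.

PC is computed on the NSCT low-frequency subimages, not on the raw images,
so the selector sees exactly the band it is fusing.

## Fusion rules and tie handling

The low rule's equality branch (`PC^A = PC^B → average`) is measure-zero in
floating point; `pcTieTolerance` (default 1e-9) operationalises it so the
averaging branch is reachable and testable. The high rule's `≥` resolves
exact energy ties to source A, which makes `fuse(A, B)` and `fuse(B, A)`
differ only at tie pixels. Selection maps (1 = A, 2 = B, 0 = averaged) are
retained per subband in the `FusionResult` for inspection.

Two invariants follow from the construction and are tested: fusing an image
with itself returns it (all rules degenerate to identity under perfect
reconstruction), and every fused coefficient is a copy of one source's
coefficient or (low band only) the two-source mean — selection, never
invention.

## Metrics

All histogram-based metrics quantize to 256 integer gray levels (8-bit
semantics) and use base-2 logs.

- **STD**: population standard deviation (divisor `M0·N0`).
- **Q^AB/F**: Sobel gradients (replicated borders); strength preservation
  is the min/max gradient ratio and orientation preservation the
  normalised angular agreement, each passed through the standard sigmoid
  models (Γ = 0.9994, κ = −15, σ = 0.5; Γ = 0.9879, κ = −22, σ = 0.8),
  multiplied, and averaged with gradient-strength weights. Flat source
  pairs have no edge information to preserve; the measure is defined as 0
  there, with a warning.
- **MI**: `MI_AF + MI_BF` from joint/marginal gray-level histograms.
- **Cross entropy**: `Σ P log2(P/Q)`; bins with `P = 0` contribute 0, and
  empty fused bins facing occupied source bins are floored at `Q = 1e-12`
  to keep the sum total. The two-source value is the arithmetic mean of
  `CE(A, F)` and `CE(B, F)` — the printed definitions leave the
  combination open, and the mean keeps the value on the single-pair scale.
- **Spatial frequency**: RMS first differences along rows and columns. The
  printed index ranges would reference pixels at index −1; sums here run
  over valid interior differences with the full `M0·N0` normalisation, so
  an alternating 0/255 image of width `N0` gives
  `RF = 255·√((N0−1)/N0)`.
- **PSNR**: `10·log10(255²/MSE)`, `Inf` when `F = ref`.

Each metric is verified against an independent double-loop oracle at 1e-10
on small seeded images.

## The synthetic test bed

`makePhantomPair()` emulates what matters about a registered multimodal
pair while staying fully deterministic: both modalities share one outer
geometry (an elliptical rim); modality A renders dense bone-like content
(bright rim, compact high-intensity blobs, a midline bar, lightly
smoothed); modality B renders soft-tissue-like content (dim rim, smooth
interior, broad low-contrast blobs, band-limited texture). Structures are
split between the modalities (`numBlobs = 6`, `contrastSplit = 0.5`), so
each source holds information the other lacks. The `composite` (per-pixel
maximum) is a convenient full-information reference for ordering
experiments. Noise corruption adds zero-mean Gaussian noise with
`σ = sigmaFraction × 255` — `sigmaFraction = 0.05` encodes a "5 %"
corruption as 5 % of the 8-bit dynamic range (12.75 gray levels), the base
being otherwise unspecified — then clips to [0, 255].

What the phantom does *not* emulate: anatomically realistic tissue
boundaries, modality-specific noise statistics (Rician MR noise, CT streak
artifacts), partial-volume effects, or misregistration. Tests passing on
phantoms therefore demonstrate the *mechanics* (exact reconstruction,
invariances, rule semantics) and the *relative ordering* of rule sets under
controlled complementary content and additive noise — not absolute clinical
image quality.

## Problem sizes and reproducibility

The test suite and the acceptance script run phantoms at 64×64 (the
smallest size at which the 3-level transform and its direction counts are
meaningful) with 10 replicate seeds for the ordering experiments; the CLI
demo defaults to 256×256, the size typical of single-slice brain
acquisitions. All stochastic steps are seed-parameterised and restore the
caller's RNG state; identical seeds give bit-identical phantoms, noise
fields and fused outputs.

## Known limitations

- Exactly two source images; no registration, color handling, or 3-D/4-D
  volumes.
- The directional bank is the frequency-windowed realization; spatial
  ladder ("pkva"-style) filters are not provided.
- PC constants (`W`, `T` estimator) follow standard practice; the measure's
  absolute scale is implementation-specific, which is harmless here because
  the fusion rule only compares PC values *between* the two sources
  computed with identical settings.
- Metric absolute values on real clinical pairs depend on acquisition
  specifics; cross-method comparisons should be made within one data set.
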