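---
title: "Methods: calibrated RGB-to-spectrum reconstruction and narrow-band simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated RGB-to-spectrum reconstruction and narrow-band simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savelight)
```

This vignette is the package's own account of its science: the model it
fits, the assumptions it leans on, the parameters that matter, what the
synthetic-data layer does and does not emulate, and the numerical choices
that make results reproducible.

## The problem

A white-light endoscopy camera integrates the scene's reflectance spectrum
against three broad sensitivity curves, then gamma-encodes and quantises the
result. Most spectral detail — in particular the sharp haemoglobin absorption
bands at 415 and 540 nm that make superficial vessels visible — is collapsed
into three numbers per pixel. The package estimates the inverse map: from an
8-bit RGB triple back to a plausible reflectance spectrum $R(\lambda)$ on a
fixed grid, calibrated per camera from a single 24-patch colour-checker
capture. From the reconstructed spectra it then synthesises narrow-band
pseudo-colour images.

The inverse problem is ill-posed — infinitely many spectra share one RGB
triple — so the model restricts solutions to the span of a principal-component
basis learned from the chart. Everything the method can and cannot do follows
from that restriction; see *Limitations*.

## The calibration model

Write $V$ for the variable matrix whose rows are polynomial expansions of
dark-subtracted, gamma-linearised patch RGB values. The fit proceeds in
three least-squares stages, each solved through a singular-value
pseudo-inverse:

1. **Colorimetric reference.** Patch reflectances $R_j(\lambda)$ become
   tristimulus values by left-anchored Riemann sums over 400–700 nm,
   $X_j = k\sum_\lambda S(\lambda) R_j(\lambda)\bar x(\lambda)\Delta\lambda$
   (likewise $Y, Z$), with
   $k = 100 / \sum_\lambda S(\lambda)\bar y(\lambda)\Delta\lambda$ so a
   perfect reflector reads $Y = 100$ under any positive illuminant. The
   normalisation is exact by construction; the test suite checks it to
   $10^{-9}$ across five illuminants.
2. **Colour correction.** $C = \mathrm{XYZ}^\top\,\mathrm{pinv}(V^\top)$
   maps expanded camera variables to reference colours; corrected colours
   are $C\,v$ per row $v$.
3. **Spectral transform.** Mean-centred PCA of the chart spectra gives an
   orthonormal basis $B$ and per-patch scores; the transform
   $M = \mathrm{Score}^\top\,\mathrm{pinv}(V_\mathrm{colour}^\top)$
   regresses scores on the polynomial expansion of corrected XYZ. A pixel's
   spectrum is $\bar r(\lambda) + B\,M\,v_\mathrm{colour}$.

Assumptions worth stating plainly: the camera response is spatially uniform
(one correction for all pixels); the scene is lit by the calibration
illuminant; reflectances of interest lie close to the chart's spectral span;
and the camera transfer curve is known up to the choice sRGB / power-law /
linear.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| master grid | 400–780 nm, step 5 | nm | one grid for both views: colorimetric integrals use the 400–700 nm part; narrow-band correction terms reach 780 nm |
| polynomial degree | 3 | — | third order balances flexibility against overfitting a 24-patch chart; degrees 1–2 available |
| PCA components | 6 | — | the number found to carry essentially all chart variance; configurable |
| illuminant | D65 | relative SPD | the lamp spectrum of a given endoscope is rarely published; D65 is a neutral, overridable default |
| observer | CIE 1931 2° | — | the conventional colorimetric observer |
| `clip_max` | 1.2 | reflectance | reconstruction may overshoot 1; values are hard-clipped into $[0, 1.2]$ and counted rather than silently altered |
| `rcond` | 1e-10 | — | singular-value cutoff of the pseudo-inverse; makes rank-deficient fits reproducible minimum-norm solutions |
| passbands | 415/30, 540/20 | nm centre/FWHM | haemoglobin absorption maxima; widths are interference-filter-like choices, the vendor's exact filters being proprietary |
| correction bands | 600, 700, 780 (650 optional) | nm | additive Cauchy-shaped terms, amplitude 0 until colour matching tunes them |
| FSA schedule | $T_k = T_0/(1+k)$, $T_0 = 1$, $10^4$ iterations | — | fast cooling with heavy-tailed Cauchy proposals of scale `step_scale`·$T_k$ (default 0.5); Metropolis acceptance $e^{-\Delta/T_k}$ |

## Numerical choices

- **Quadrature** is a left-anchored Riemann sum with uniform weight
  $\Delta\lambda$, the way tabulated observer curves are conventionally
  summed; results are bit-reproducible.
- **Gamma.** The IEC 61966-2-1 sRGB piecewise transfer is the default
  decode; a pure power law and identity are available because camera
  pipelines differ. Encoding inverts decoding exactly on all 256 codes.
- **Variable matrix membership.** The split of correction terms into
  colour / non-linear / dark groups is not standardised; this package uses
  the full graded-lexicographic monomial set over $(r, g, b)$ up to degree 3
  plus a constant (20 terms) on dark-subtracted, linearised channels, and
  records the grouping as term labels only.
- **Conditioning.** The cubic expansion of corrected XYZ is computed on
  XYZ/100, keeping monomials $O(1)$; linear relations stay exactly
  representable, so noiseless recovery is unaffected.
- **PCA conventions.** Mean-centring is mandatory; each component's
  largest-magnitude coefficient is made positive so signs are deterministic;
  explained-variance fractions are reported against total variance.
- **PCA range.** Components are computed on the full 400–780 nm grid (the
  spectra the cube must reproduce extend to 780 nm); restricting to
  400–700 nm is possible by building the chart on a shorter grid.
- **CIEDE2000** follows the published reference algorithm with
  $k_L = k_C = k_H = 1$, including all hue-angle branch cases; the suite
  pins it to an independent implementation on the 34 published verification
  pairs at $10^{-4}$.
- **Similarity index.** The agreement score between spectrometer and
  estimated XYZ is defined here as $1 - \mathrm{RMSE}/\mathrm{RMS}$ of the
  reference, clamped to $[0,1]$ — an artifact definition, flagged as such.
- **Average precision** integrates the precision–recall step curve with
  right-continuous interpolation (no 11-point smoothing); mean AP averages
  over classes. Ties in scores keep input order.
- **SSIM** uses the standard 11×11 Gaussian window ($\sigma = 1.5$),
  $K_1 = 0.01$, $K_2 = 0.03$, unit data range, border crop of half a
  window; the implementation is cross-checked against an independent one on
  a frozen fixture.
- **Entropy difference** is $|H_a - H_b|/H_b \times 100$ on 256-bin
  greyscale histograms — again artifact-defined, since "picture entropy"
  has no single convention. Identical images give 0; a constant reference
  image gives an `Inf` sentinel rather than a silent 0.
- **Zero denominators** in precision/recall are reported as 0 with an
  `undefined` flag instead of an error, keeping batch evaluation alive.
- **Serialisation.** Calibration bundles and narrow-band specs are JSON with
  numbers at 17 significant digits, so save→load is `identical()`; cubes are
  ENVI-style text headers plus band-sequential floats, 64-bit by default so
  write→read round-trips bit-exactly (32-bit offered for interoperability).
- **Degenerate inputs** are rejected with messages naming the offending
  value: non-divisible grid steps, zero illuminants (undefined $k$),
  all-zero variable matrices, alpha channels (rejected, never silently
  dropped), out-of-range channel codes.

## The synthetic-data layer

The generator exists so every oracle and recovery test can run offline.

**Chart.** The packaged 24-patch chart is an affine family over three smooth
shapes — a flat base, a logistic red edge, a blue Gaussian bump — with 18
chromatic patches spanning the red/green/blue/cyan/magenta/yellow families
and 6 exactly flat greys, all inside $[0, 1]$. Three shapes is a deliberate
design decision, not a convenience: tristimulus XYZ carries three degrees of
freedom, so patch scores can only be an exact function of patch colour when
the chart spans at most three spectral dimensions. A higher-dimensional
chart would contain metamer pairs the score regression cannot separate, and
the noiseless construct-and-recover oracle (reconstruction RMSE $<10^{-6}$)
would be unattainable for information-theoretic reasons rather than
implementation ones. The trade-off is documented under *Limitations*;
measured charts with higher intrinsic dimension load via
`read_chart_reference()`.

**Camera.** `make_camera_model()` exposes spectral sensitivities, transfer
curve, additive Gaussian noise on the linear signal (applied before gamma,
the physical order), per-channel dark offset, and quantisation depth. The
`ideal` preset (observer curves as sensitivities, linear transfer, no noise,
no dark, no quantisation — patch captures are patch-region means and thus
effectively continuous) makes captures exactly linear in XYZ, which is what
the exact-recovery oracles require. The `realistic` preset (shifted Gaussian
sensitivities at 600/540/465 nm, sRGB transfer, noise sd 0.01, dark 5,
8-bit round-half-even quantisation) drives the directional tests: across
seeds, the corrected mean $\Delta E_{00}$ must drop below the uncorrected
one.

**Scenes.** `synth_endoscopy_scene()` builds a smooth pink mucosa
reflectance with sinuous vessels whose pixels are attenuated by Gaussian
dips at 415 and 540 nm (depth 0.5 by default, the 540 nm dip at 0.8× that).
The scene supports exactly one falsifiable claim — narrow-band vessel
contrast exceeds white-light contrast — and the suite checks it via
Michelson contrast on the two renders.

What the generator does **not** emulate: specular highlights, vignetting,
spatially varying illumination, chromatic aberration, motion blur, sensor
cross-talk, demosaicing, JPEG artefacts, and real tissue optics beyond
parametric dips. Passing tests therefore show the algorithm is implemented
correctly and behaves directionally as intended; they do not certify
performance on clinical frames.

## Problem sizes

Defaults were chosen once, as ordinary desk-scale experiment sizes: 24-patch
charts, 48×48-pixel scenes, 77-band cubes, $10^4$ annealing iterations,
5-seed repetitions for directional claims. The acceptance script's reported
quantity (tristimulus normalisation) uses the 61-sample 400–700 nm grid.

## Limitations

- **Basis span.** Reconstruction lives in the chart's spectral span. The
  packaged chart spans three dimensions, so narrow features — the very
  haemoglobin dips narrow-band imaging exploits — cannot be recovered from
  an RGB triple that never saw them; reconstructed scene spectra are smooth
  approximants and the re-rendered white-light loop loses vessel structure
  (visible as low SSIM in the README example). This is a property of
  chart-based RGB-to-spectrum inversion in general: with any chart, only
  three numbers per pixel enter the inverse map.
- **Metamerism.** Distinct spectra with equal corrected XYZ reconstruct
  identically, by construction.
- **Single illuminant.** Calibration and reconstruction assume the same
  light; no chromatic-adaptation transform beyond white-point normalisation
  is applied.
- **Clipping.** Out-of-range reconstructed reflectance is clipped into
  $[0, \mathrm{clip\_max}]$ and counted; heavy clipping (reported in the
  cube header) signals inputs far from the calibration gamut.
- **No per-frame renormalisation** of reconstructed reflectance is applied;
  cubes are directly comparable across frames from the same bundle.
- **Colour matching** optimises patch-level colours; it does not guarantee
  pixel-level agreement with vendor hardware, whose display mapping is
  proprietary.
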