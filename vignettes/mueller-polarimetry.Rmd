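---
title: "Decomposing Mueller-matrix images of layered birefringent tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing Mueller-matrix images of layered birefringent tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerpol)
```

## The measurement and the two models behind it

A transmission Mueller microscope records, at every pixel, the 4x4 real
matrix $M$ that maps input to output Stokes vectors $(I, Q, U, V)$. For
thin sections of fibrous tissue such as brain white matter, the three
quantities of interest are the net scalar retardance $R_t$ (the phase
lag accumulated between orthogonal polarization eigenmodes, which
tracks how much aligned fiber the light crossed), the azimuth
$\theta$ of the optical axis (the in-plane fiber direction, periodic
with period 180 degrees), and the depolarization $\alpha_t$ (loss of
polarization degree through scattering). `muellerpol` computes all
three with two independent decompositions and provides a forward
simulator of layered retarders to validate every stage against known
ground truth.

The two decompositions embody different physical pictures:

* **Differential decomposition** assumes the polarimetric effects act
  *continuously* along the propagation path: $dM = m\,M\,dz$. The
  accumulated generator is the matrix logarithm $L = \ln M$, computed
  per pixel from the eigendecomposition of $M$ on the principal
  branch. $L$ splits under the Minkowski metric
  $G = \mathrm{diag}(1, -1, -1, -1)$ into
  $m_m = \tfrac12 (L - G L^T G)$ (G-antisymmetric, the mean dichroism
  and birefringence) and $m_u = \tfrac12 (L + G L^T G)$ (G-symmetric,
  depolarization and property uncertainties). The six elementary
  properties $p_1 \ldots p_6$ (linear dichroism along x-y and +-45
  degrees, circular dichroism, linear birefringence along x-y and
  +-45 degrees, circular birefringence) sit at fixed positions of
  $m_m$; the depolarizing diagonal $\alpha_0 \ldots \alpha_3$ and the
  uncertainties $d_1 \ldots d_6$ sit in $m_u$. The summaries are
  $R_t = \sqrt{p_4^2 + p_5^2 + p_6^2}$,
  $\alpha_t = |\alpha_1 + \alpha_2 + \alpha_3| / 3$, and
  $\theta = \tfrac12 \operatorname{atan2}(p_5, p_4)$.

* **Lu-Chipman (polar) decomposition** assumes the effects act
  *sequentially*: $M = M_\Delta M_R M_D$, a diattenuator followed by a
  retarder followed by a depolarizer. $M_D$ is assembled from the
  normalized first row of $M$; $M' = M M_D^{-1}$ is split by taking
  the signed symmetric square root
  $m_\Delta = \pm(m' m'^T)^{1/2}$ (sign of $\det m'$), and
  $M_R = M_\Delta^{-1} M'$. The summaries are
  $R_t = \cos^{-1}[\mathrm{tr}(M_R)/2 - 1]$,
  $\alpha_t = 1 - (|a| + |b| + |c|)/3$ from the principal-frame
  diagonal of $m_\Delta$, and the azimuth from the retardance vector
  of $M_R$.

Both run behind one image-level driver, `decompose_image()`, after
m11-normalization, optional substrate correction, and Cloude
filtering.

## Conventions, and two deliberate formula choices

The azimuth is measured counterclockwise from the laboratory x-axis
looking toward the source and reported in degrees on $[0, 180)$; the
Stokes convention is $(I, Q, U, V)$. Within this frame the retarder
constructor `retarder_mueller()` and both decompositions are mutually
consistent: composing and decomposing recovers the generator azimuth
exactly, which the test suite checks at $10^{-9}$ degrees.

Two places where the package deliberately deviates from formulas that
circulate in the applied literature:

1. **Differential azimuth.** The ratio form
   $\theta = \tfrac12 \tan^{-1}(p_5 / p_6)$ sometimes quoted for the
   differential decomposition divides by the *circular* birefringence
   $p_6$. For a linear retarder at azimuth $\theta$ the generator
   satisfies $p_4 = \delta \cos 2\theta$,
   $p_5 = \delta \sin 2\theta$, so the linear-birefringence azimuth is
   $\tfrac12 \operatorname{atan2}(p_5, p_4)$. We treat the $p_6$
   denominator as a typo and implement the $p_4$ form, with the
   two-argument arctangent to resolve the quadrant.

2. **Lu-Chipman azimuth and retardance.** The textbook ratio
   $M_R(2,4) / M_R(4,3)$ is exact only for *pure linear* retarders.
   Two stacked layers with different axes compose to a slightly
   elliptical retarder, and on such pixels the ratio form disagrees
   with the differential azimuth by up to about 0.8 degrees. The
   package instead extracts the retardance vector from the
   antisymmetric part of the rotation block,
   $\theta = \tfrac12 \operatorname{atan2}(M_R(2,4) - M_R(4,2),\,
   M_R(3,4) - M_R(4,3))$, which reduces to the ratio for linear
   retarders and is generator-exact for elliptical ones; with it the
   two methods agree to $10^{-13}$ degrees on noiseless scenes.
   Similarly $R_t$ is evaluated as
   $\operatorname{atan2}(|w|, (\mathrm{tr}\,m_R - 1)/2)$ with $w$ the
   rotation's axis vector - identical to the arccosine form for exact
   rotations, but accurate to machine precision near $R_t = 0$, where
   $\cos^{-1}$ of a rounded trace loses half the significant digits
   (the arccosine form cannot certify the crossed-equal-retarder
   compensation below $10^{-6}$ degrees; the axis-angle form can).

The azimuth is reported as `NaN` wherever the retardance (or its
linear part) is negligible, since no axis is defined there.

## Physical realizability filtering

Measured Mueller matrices are noisy and need not be physically
realizable. The Cloude criterion maps $M$ linearly to a Hermitian
coherency matrix $H = \tfrac14 \sum_{ij} m_{ij}\,
(\sigma_i \otimes \sigma_j^*)$ and requires $H \succeq 0$.
`cloude_filter()` clamps negative eigenvalues of $H$ to zero and maps
back. Two choices were open and are both exposed:

* the clamped spectrum is *not* renormalized by default (the filter
  then never touches a physical matrix and is exactly idempotent);
  `renormalize = TRUE` preserves the trace (total intensity) instead;
* the tolerance is relative, `min eigenvalue >= -tol * trace(H)` with
  `tol = 1e-6`, well below a one-percent instrument accuracy.

## The matrix logarithm

The per-pixel logarithm follows the eigendecomposition route
($L = V \ln(D) V^{-1}$), which is the natural choice for
diagonalizable 4x4 matrices and fails in exactly the physically
meaningful case: an eigenvalue on the closed negative real axis
(strong scattering), where the principal branch does not exist. Such
pixels are flagged `decomposition-failed` rather than silently
mis-decomposed. When the eigenvector matrix is too ill-conditioned to
certify the result (the eigen-reconstruction of $M$ is checked at
$10^{-10}$ and the imaginary residue at $10^{-9}$), the routine falls
back to an inverse-scaling-and-squaring iteration (Denman-Beavers
square roots plus a Mercator series). The test suite cross-checks the
logarithm against an independently written Gregory-series oracle and
against `Matrix::expm` round trips at $10^{-8}$ on 500 random
physical matrices.

## What the simulator emulates - and what it does not

`generate_image()` builds scenes as stacks of homogeneous layers, each
an isotropic partial depolarizer times a linear retarder:

| parameter | unit | preset default | rationale |
|---|---|---|---|
| `thickness_um` | um | 10 (bottom), 5 (top) | nominal section thicknesses of the emulated stacks |
| `retardance_deg_per_um` | deg/um | 1.8 | makes the 10 um layer's total retardance 18 deg, the single-section anchor value |
| `azimuth_deg` | deg | 90 (single), 110 (stack) | observed median fiber directions of the emulated arrangements |
| `azimuth_jitter_deg` | deg | 6 | spatial SD giving an azimuth spread comparable to the reported single-section box plots |
| `retardance_cv` | - | 0.15 | lognormal, median-preserving; a realistic tissue-heterogeneity scale |
| `depol_per_um` | 1/um | 0.01 (bottom), 0.035 (top) | see below |
| `hole_fraction` | - | 0.10 (single), 0.03 (stack layers) | "no tissue" zones; parallel overlap reduces exposed holes |
| `element_sigma` | - | 0.0221 | detector noise; see below |

Spatial heterogeneity is smoothed white noise (Gaussian kernel,
SD 3 px by default): real azimuth maps are spatially structured, but
no generative model for that structure is claimed - the smoothing
scale is a free, documented parameter. Holes are random disks inside
which a layer contributes the identity. Noise is added to the
normalized elements *after* composition, which is where detector noise
enters physically.

**Depolarization rates.** Measured depolarization grows superlinearly
with stack thickness (roughly 2.5-3x when going from a 10 um section
to a 10+5 um stack), which a single linear rate cannot reproduce: with
one rate $k$, the generator-scale depolarization ratio is exactly
$15k/10k = 1.5$. The presets therefore give the thinner top stripe a
higher rate per micrometre (0.035 vs 0.01 /um), giving ratios of 2.75
(differential scale) and about 2.5 (Lu-Chipman scale). This mimics the
empirical thickness dependence; it is a calibration, not a scattering
model.

**Noise calibration.** The stated instrument accuracy of 2-3 degrees
of retardance is read as a bound: on a blank (identity) pixel the
spurious retardance induced by element noise follows a scaled
chi-distribution with three degrees of freedom, and `element_sigma`
is set so its 95th percentile is 2.5 degrees
(`calibrate_noise_floor()` reproduces this empirically through the
full filter-plus-decomposition chain). Azimuth statistics exclude
pixels below a 3-degree retardance floor by default - the upper end of
the accuracy band, a conservative exclusion; the floor is a parameter
(`floor_deg`), and setting it to zero reproduces the
inflated-spread behaviour seen when noise-dominated pixels are kept.

The simulator deliberately omits: volumetric scattering
(depolarization is a diagonal attenuation, not a radiative-transfer
result), anisotropic depolarization, diattenuation (real tissue shows
a little; the pipeline computes and stores $D$ but the generator does
not produce it), reflection geometry, and any wavelength dependence.
Passing tests on synthetic scenes therefore validate the *algebra and
statistics* of the pipeline, not the biophysics of scattering tissue.

## Scene-level behaviour worth knowing

* **Crossing-angle monotonicity.** For two co-planar-axis layers with
  retardances $\delta_1 > \delta_2$, the composed retardance falls
  strictly from $\delta_1 + \delta_2$ at parallel overlap to
  $\delta_1 - \delta_2$ at 90 degrees; for equal layers it reaches
  zero (exact compensation). The rotation-composition closed form is
  $\cos(R_t/2) = \cos(\delta_1/2)\cos(\delta_2/2) -
  \sin(\delta_1/2)\sin(\delta_2/2)\cos 2\gamma$ for crossing angle
  $\gamma$.
* **A 45-degree crossing does not drop below the single layer.** With
  $\delta_1 = 18$, $\delta_2 = 9$ degrees, the 45-degree stack
  composes to $2\cos^{-1}(\cos 9^\circ \cos 4.5^\circ) \approx
  20.1^\circ$, *above* the 18-degree single layer: at 45 degrees the
  retardance vectors add nearly in quadrature. The median ordering on
  the four preset scenes is therefore parallel > crossed45 > single >
  crossed90, and that is what the tests assert. Observed orderings in
  which every rotated stack sits below the parallel one are consistent
  with this; an ordering that put a 45-degree stack below the single
  section would require unequal effective layer retardances.
* **Azimuth randomization at 90 degrees.** For two *identical* stripes
  (same spatial realization: `share_layer_fields = TRUE`) crossed at
  90 degrees, compensation is exact pixel-wise and only the noise
  floor remains: fewer than 10 percent of pixels survive the 3-degree
  azimuth floor, reproducing the loss of preferential orientation. For
  two *independent* stripes the residual $|\delta_1 - \delta_2|$ field
  keeps many pixels above the floor - the distinction matters and the
  generator exposes it as a flag.
* **Depolarization conventions.** For isotropic depolarization
  strength $a$ the two scales are exactly
  $\alpha_t^{LC} = 1 - a$ and $\alpha_t^{diff} = -\ln a$, hence
  $\alpha_t^{diff} = -\ln(1 - \alpha_t^{LC})$ and the Lu-Chipman
  values always run lower on heterogeneous scenes while ranking pixels
  identically (rank correlation 1 on noiseless data).

## Statistics and reporting

Box-whisker summaries use type-7 (linear interpolation) quartiles and
Tukey 1.5 x IQR whiskers; on `{1, 2, 3, 4, 100}` this gives quartiles
2 and 4 and one outlier. Azimuth summaries default to linear quantiles
on $[0, 180)$ - matching how such distributions are usually plotted -
with a circular (doubled-angle centring) alternative for distributions
straddling the wrap point. Quiver exports sample every 20th pixel by
default and normalize stick length by the maximum retardance of the
map. All summaries are invariant under permutation of the valid
pixels, and the whole pipeline is deterministic given the input.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script use 64x64-pixel scenes for
statistical checks, 32x32 or 48x48 where only per-pixel algebra is
exercised, 500-1000 random matrices for oracle comparisons, and 400+
blank pixels for the noise-floor calibration; these sizes give medians
stable to a fraction of a degree across seeds while keeping a full run
in tens of seconds. Degenerate inputs are handled per pixel: `m11 <= 0`
masks the pixel as non-physical; total diattenuation ($D \ge 1$) and a
singular depolarizer block (complete depolarization along an axis)
leave the remaining factors defined but flag the retarder outputs
invalid; an undefined principal logarithm flags the pixel
`decomposition-failed`. Image-level loops never abort on a bad pixel.

## File formats

Images travel as multi-page float32 TIFF: 16 bands in row-major
element order m11 ... m44, band-sequential, with wavelength, pixel
size and provenance as JSON in the first page's ImageDescription.
Derived maps use the same container plus a validity band and a CSV
sidecar of box-whisker rows. The codec is written into the package
because the available TIFF bindings only store data normalized to
[0, 1]; it emits plain uncompressed little-endian TIFF readable by
standard scientific readers.

## Known limitations

* Retardances are reported on the principal branch $[0, 180]$
  degrees; the simulator keeps ground truth below 180 degrees, and no
  unwrapping is attempted.
* The differential path fails (by construction) where an eigenvalue
  reaches the negative real axis; in transmission through thin
  sections this is rare, but strongly scattering or reflection-mode
  data would need the Lu-Chipman path alone.
* Depolarization in the simulator is isotropic; anisotropic
  depolarization would make the closed-form cross-method checks
  inexact and is intentionally out of scope.
* The reverse polar decomposition (depolarizer first) is not
  implemented.
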