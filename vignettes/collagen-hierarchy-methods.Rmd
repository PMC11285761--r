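---
title: "Methods: collagen hierarchy metrics from fiber diffraction and pSHG"
author: "collagenHier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen hierarchy metrics from fiber diffraction and pSHG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `collagenHier`, the tunable
parameters and their defaults, the numerical choices made where the
design was genuinely open, and what the synthetic studies do and do
not demonstrate about real tissue data.

# The measurement problem

Type I collagen is hierarchical: tropocollagen molecules pack
laterally at ~2.3 nm spacing inside fibrils that carry the ~67 nm
axial D-period, and fibrils in turn disperse in orientation within a
tissue. Mineralizing tendon (the turkey leg tendon model, with
non-mineralizing NM, early EM and late LM zones) changes this
organization at several scales at once. Two modalities probe it:

* **Small-angle fiber diffraction** sees both length scales in one
  pattern: meridional D-period orders near Q = 0.28 nm⁻¹ (third
  order) along the fibril axis, and an equatorial intermolecular arc
  near Q = 2.7 nm⁻¹ perpendicular to it. Azimuthal widths of the two
  features report fibril- and molecule-level orientation dispersion.
* **pSHG microscopy** measures, per pixel, the modulation of
  second-harmonic intensity under rotation of the incident linear
  polarization; the modulation depth I₂ increases with the degree of
  molecular-scale organization around the dominant direction φ₂.

# Fiber-diffraction reduction

## Geometry

Detector pixels map to reciprocal space by

  Q = (4π/λ) · sin(½ · arctan(r/L)),

with r the in-plane distance from the beam center and L the camera
length; azimuth is counter-clockwise from the detector +x axis. The
spacing convention is Q = 2π/d throughout (2.7 nm⁻¹ ↔ 2.33 nm;
0.28 nm⁻¹ ↔ 22.4 nm, the third order of 67.3 nm). `DetectorGeometry`
defaults to an Eiger2 4M-class setup (700 mm, 0.0979 nm, 75 µm
pixels, 2162 × 2068); `syntheticGeometry()` (2000 × 2000 px at
1250 mm) is used for all bundled simulations — the longer camera
length spreads the narrow D-period window over enough pixels that
every 0.5° azimuthal segment supports its own background fit, while
still covering the intermolecular window and flanks
(Q ≤ 3.85 nm⁻¹ on-axis) with a beamstop below 0.18 nm⁻¹.

## Background subtraction

Diffuse scattering from sharp interfaces falls as I ∝ Q⁻⁴ (Porod). A
straight line is fitted to (ln Q, ln I) over two flank windows
bracketing each peak window, subtracted from ln I, and the residual
exponentiated (`porodMethod = "log"`, the default; `"linear"`
subtracts exp(fit) in intensity units instead). The log-residual
I/I_fit − 1 is dimensionless and ~0 on pure background. One
consequence matters numerically: dividing a peak by Q⁻⁴ multiplies it
by Q⁴, which would displace an extracted center by ≈ 4σ²_Q/Q₀ — about
0.09 nm⁻¹ for the intermolecular arc, an order of magnitude beyond
the target accuracy. All **peak-position metrics are therefore
extracted on the intensity scale** I − I_fit (recovered exactly from
the log residual by multiplying back the fitted background); the
choice of `porodMethod` affects only the units of the stored net
signal.

Flank windows default to 20% of the peak-window width immediately
outside each edge. The per-segment azimuthal stage on the D-period
window uses 50% instead (flanks [0.20, 0.24] and [0.32, 0.36] nm⁻¹):
a 0.5° segment at that radius contains only a handful of pixels, and
the narrower flanks would leave most segments without the ≥ 3 usable
bins per flank that determine the background line. Bins with I ≤ 0
are flagged unusable; a flank that is entirely non-positive is an
error naming the flank.

## Peak metrics

* **D-period**: the third meridional order is broad and variable in
  shape near the beamstop (divergent-beam flare), so the peak
  *centroid* (intensity-weighted mean of Q over [0.24, 0.32] nm⁻¹) is
  used rather than the mode; d = 3·2π/Q̄. Orders 1–2 sit inside the
  beamstop flare region and are ignored.
* **Intermolecular spacing**: nonlinear Gaussian fit
  (A·exp(−(Q−µ)²/2σ²) + c, Levenberg–Marquardt) over
  [1.9, 3.5] nm⁻¹; d = 2π/µ. A fit that fails to converge, or whose
  center leaves the window, marks the metric missing for that
  pattern — it never aborts a scan.

Radial profiles are taken in ±20° azimuthal wedges (and their Friedel
pairs) about the preferred fibril orientation (meridional, D-period)
and 90° away (equatorial, intermolecular), binned at 0.002 and
0.02 nm⁻¹ respectively. Wedge membership is resolved at 0.5°-segment
granularity.

## Azimuthal dispersion

The angular spread of each feature is measured by splitting the
pattern into 720 segments of 0.5°, repeating the background
subtraction per segment, and summing the net peak signal per segment
(pixel-area-weighted, so segment signals partition the full-circle
net total exactly). Two numerical details:

* **Pixel splitting.** At the D-period radius a 0.5° segment
  subtends less than one pixel, and pixel centers leave structural
  holes near the lattice axes. Pixels are therefore split into n²
  equal sub-areas assigned to cells individually — the standard
  polar-rebinning device, approximated by area sampling. The factor
  is chosen automatically from the inner annulus radius (5 for the
  D-period window at the bundled geometry, 1 for the intermolecular
  window, where segments are many pixels wide).
* **FWHM.** The 720-segment profile is folded to its 180° period
  (fibre/Friedel symmetry), gaps are filled by linear interpolation,
  and the full width at half maximum is found by linear interpolation
  between bins, with ties at the half level broken toward the wider
  width. The apex is refined by a local quadratic fit over ±0.7 σ
  (from a first-pass FWHM) because the raw bin maximum rides on the
  area-sampling noise and would bias the half level high; for lobes
  wider than 5° a 3-bin circular boxcar (which widens a Gaussian lobe
  by < 0.01° at these dispersions) damps the same noise before the
  crossings are located. A lobe with no half crossing is reported as
  180° with a flag. The preferred fibril orientation is the folded
  lobe apex.

The diffuse low-Q mineral feature overlaps the D-period window in Q
but sits azimuthally perpendicular to the fibril orientation, so it
does not disturb the meridional analysis; no explicit mineral
deconvolution is attempted.

## Supramolecular twist

The molecular azimuthal dispersion convolves the fibril orientation
distribution with the intrafibrillar spread of molecules about the
fibril axis. Under a Gaussian-convolution surrogate the intrafibrillar
part is

  σ_twist = √(max(σ²_mol − σ²_fib, 0)),   σ = FWHM / 2·√(2 ln 2),

clamped at zero (with a flag) when the molecular dispersion is the
narrower. This quadrature deconvolution replaces the full scattering
model used in beamline practice; like that estimate it is read as a
*relative* quantity, reported per pattern after normalization by the
mean raw twist of the NM reference region (so the NM mean is 1 by
construction). The full scattering-model inversion is out of scope.

## Scan handling

Patterns below a configurable total-count gate (default 10³) are
skipped with a `low_signal` flag; all per-pattern failures propagate
as missing fields. `binScanHorizontal()` sums consecutive groups of
`factor` patterns along x within each scan row (trailing remainders
dropped, positions replaced by group centers), reproducing the
signal-to-noise binning of a 20 µm-pitch snake scan into 100 µm
columns; `binScanPositions()` is the positions-only bookkeeping form.

# pSHG circular-harmonic analysis

Per pixel, intensity as a function of polarization angle α is
projected onto {1, cos 2α, sin 2α, cos 4α, sin 4α} by ordinary least
squares (the acquisition default of 12 angles at 15° covers one 180°
period and determines the five coefficients uniquely; rank is checked
at fit time). Amplitudes come from the quadrature pairs, so they are
non-negative by construction:

* a₀ — constant term, the mean of I(α);
* I₂ = √(c₂² + s₂²)/a₀, φ₂ = ½·atan2(s₂, c₂) ∈ [0°, 180°);
* I₄, φ₄ analogously with ¼·atan2 into [0°, 90°).

I₂ is reported normalized by a₀: the tissue values this pipeline
targets (0.21–0.33) are dimensionless and intensity-independent, and
a₀ is the natural scale of the response. Whether the published
quantity is amplitude/a₀ or the raw amplitude of a pre-normalized
curve is not fully determined by its description; the normalized
reading is adopted and the unnormalized amplitude is stored
alongside (`amp2Map`). I₄/φ₄ are computed and stored but excluded
from region summaries. Least squares is unweighted — no noise model
is assumed; pixels with fitted a₀ ≤ 0 are masked.

An intensity threshold masks pixels too dim for a reliable fit: by
default a pixel is kept when its mean intensity over angles reaches
10% of the 99th percentile of the mean-intensity image. Region
summaries aggregate in two levels, exactly as acquired: mean I₂ over
unmasked pixels per acquisition first, then mean and sample standard
deviation (n − 1) across acquisitions; a single-acquisition region
reports sd 0 with a flag, and acquisitions with no valid pixels are
excluded with a message.

# Region statistics

One-way ANOVA (delegated to `stats::aov`) followed by Tukey–Kramer
post hoc comparisons: for groups i, j,

  q = |x̄ᵢ − x̄ⱼ| / √( MSW/2 · (1/nᵢ + 1/nⱼ) ),

with the adjusted p from the studentized-range distribution
(`stats::ptukey`, accurate well beyond four decimals) on (k, N − k)
degrees of freedom; unequal group sizes are the Kramer case. Pairs
involving a singleton group are flagged untestable. Significance
stars follow the 0.05/0.01/0.001/0.0001 tiers. XRD metrics are
compared at per-pattern granularity; pSHG at per-acquisition-mean
granularity — the two are never pooled. Zero-variance degenerate
input (all values identical) is an explicit error, since F is
undefined.

# The synthetic study

## What the generators emulate

A scatter scene is the sum of a Porod background c·Q⁻⁴; meridional
D-period orders 1–3 (Gaussian in Q, σ_Q = 0.01 nm⁻¹) with a wrapped
Gaussian azimuthal profile of width σ_fib about the preferred
orientation; an equatorial intermolecular arc (σ_Q = 0.15 nm⁻¹) with
azimuthal width √(σ²_fib + σ²_twist), encoding the convolution
picture the twist estimate inverts; a diffuse mineral lobe; a
circular beamstop (masked pixels, sentinel −1 on disk); and optional
Poisson noise, all seeded explicitly — no global random state. The
intermolecular σ_Q is set so that the arc stays inside the
1.9–3.5 nm⁻¹ window and clear of its background flanks down to the
smallest region spacing (2.13 nm → Q ≈ 2.95 nm⁻¹); a wider arc would
leak into the outer flank, where the Q⁻⁴ background is weakest, and
corrupt the per-segment background fits.

No functional form is established for the mineral scatter lobe; it
is a **synthetic stand-in**: a Gaussian at Q = 0.45 nm⁻¹
(σ_Q = 0.25 nm⁻¹, azimuthal σ = 25°) centered perpendicular to the
fibril orientation, scaled by `mineralFraction`. It overlaps the
D-period window in Q while decaying to negligible levels below the
intermolecular flanks — matching the observed phenomenology that the
mineral feature does not perturb either peak analysis.

The region defaults (`regionScatterScenes()`) encode the tissue
ground truth this pipeline targets: D-periods 66.92/67.46/67.21 nm,
spacings 2.37/2.16/2.13 nm and fibril dispersion FWHMs
31.19/15.31/19.88° for NM/EM/LM. Twist sigmas are 8.79° for NM —
quadrature-consistent with the NM molecular FWHM of 37.43° — and
scaled for EM/LM by the relative-twist ratios (0.72/0.98, 0.68/0.98
→ 6.46°, 6.10°). The reported EM/LM molecular FWHMs are not exactly
quadrature-consistent with the corresponding fibril FWHMs and
relative twists (they derive from a different scattering model), so
the scenes imply molecular FWHMs of 37.4/21.6/24.5°; every ordering
between regions is preserved. pSHG region scenes use I₂ =
0.21/0.29/0.33 at a₀ = 500 counts, with an optional per-acquisition
I₂ jitter (defaults in the demo pipeline: σ = 0.044/0.043/0.038)
emulating between-acquisition variability for the statistics stage.

## What they do not emulate

Beam divergence and beamstop flare (the real cause of the blunted
third-order peak), detector point-spread and flat-field structure,
molecular structure factors and Lorentz/polarization corrections,
sample thickness effects, spatial autocorrelation between neighboring
scan positions, mineral crystallography, waveplate imperfections and
birefringence residuals, and the TPEF channel. Passing tests
therefore demonstrate that the *estimators* are correct and well
conditioned for data of the stated geometry and noise character — not
that they are robust to every instrumental artifact of real
beamlines; on real tissue the twist and dispersion values should be
read as relative trends, as the estimator's own derivation assumes.

# Numerical defaults

| Parameter | Default | Units | Notes |
|---|---|---|---|
| D-period window | 0.24–0.32 | nm⁻¹ | third meridional order |
| Intermolecular window | 1.9–3.5 | nm⁻¹ | equatorial arc |
| Usable Q range | 0.2–5 | nm⁻¹ | windows validated inside it |
| Radial flank fraction | 0.2 | — | of the window width, each side |
| Azimuthal flank fraction (D) | 0.5 | — | segment fits need ≥3 bins/flank |
| Azimuthal segments | 720 × 0.5 | deg | folded to 180° before FWHM |
| Radial wedge half-width | 20 | deg | about the preferred orientation |
| Radial bin width (D / IM) | 0.002 / 0.02 | nm⁻¹ | |
| Segment q-bins (D / IM) | 4+8+4 / 6+16+6 | — | flank+peak+flank |
| Min counts gate | 1000 | counts | per pattern |
| pSHG threshold | 0.10 × P99 | — | of the mean-intensity image |
| pSHG angles | 0, 15, …, 165 | deg | 12 angles, one 180° period |
| Significance tiers | .05/.01/.001/.0001 | — | star annotations |

Degenerate inputs are handled by flagging, not failure: missing
sub-metrics propagate as NA fields, profiles with more than half
their segments unusable are rejected, flat azimuthal profiles report
a flagged 180° width, and clamped twists are flagged.

# Problem sizes

The bundled studies run at desk scale by design: the parameter-
recovery study uses a 20 × 20 scan (400 patterns, ~130 per region) at
the 2000 × 2000 px synthetic geometry; pSHG recovery uses four
512 × 512 × 12 shot-noise acquisitions per region at a₀ = 500; the
type-I calibration uses 2000 null replicates of three groups of 10.
The demo pipeline (`runPipeline()`) reduces a 2 × 6 Poisson-noise
scan and fits 6/4/4 acquisitions per region, mirroring the
acquisition design of a full tissue study at reduced raster size.

# Known limitations

* The twist estimate is a relative, model-surrogate quantity; its
  absolute scale is not calibrated against the full scattering model.
* The centroid D-period estimator is robust to blunt peaks but
  inherits a small bias if the background fit is tilted by features
  entering the flanks; with the bundled windows this is below 0.1 nm.
* Wedge membership and preferred orientation are resolved at 0.5°
  granularity; orientation equivariance holds to about that scale.
* The per-segment background fit requires flank coverage; at
  geometries much coarser than the bundled one (e.g. short camera
  lengths) low-Q segments become undetermined and are flagged — the
  reduction then degrades gracefully but loses azimuthal resolution.
* TIFF rasters store 32-bit scaled codes: integer count data
  round-trip exactly; float data to ~1e-10 relative.
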