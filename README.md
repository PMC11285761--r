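# collagenHier

Dual-modality analysis of collagen hierarchical organization in
mineralizing tendon, for researchers working with synchrotron
small-angle fiber diffraction and polarization-resolved second
harmonic generation (pSHG) microscopy of the turkey leg tendon model
(non-mineralizing NM, early-mineralizing EM and late-mineralizing LM
zones).

The package has three analysis layers plus simulators:

* **Fiber-diffraction reduction.** Each 2D scatter pattern is mapped
  to polar coordinates with Q = (4π/λ)·sin(½·arctan(r/L)) and reduced
  to five structural metrics:

  - **D-period** (~67 nm axial repeat): intensity-weighted centroid
    of the background-subtracted third meridional order in
    Q ∈ [0.24, 0.32] nm⁻¹, d = 3·2π/Q̄;
  - **intermolecular spacing** (~2.3 nm): Gaussian fit of the
    equatorial peak in Q ∈ [1.9, 3.5] nm⁻¹, d = 2π/Q₀;
  - **fibril and molecular dispersion**: FWHM of the azimuthal
    distribution of each feature, from 720 half-degree segments with
    per-segment Porod background subtraction (the background
    I ∝ Q⁻⁴ is removed by fitting a line to ln I vs ln Q on flanks
    either side of each peak);
  - **relative supramolecular twist**: the quadrature excess
    √(σ²_mol − σ²_fib) of molecular over fibril dispersion
    (σ = FWHM/2.355), normalized to the NM-region mean.

* **pSHG circular-harmonic fitting.** Per pixel of a 512 × 512 × 12
  polarization stack, ordinary least squares on
  I(α) = a₀ + I₂·cos 2(α − φ₂) + I₄·cos 4(α − φ₄) gives the
  organization parameter I₂ (reported as the 2α amplitude / a₀) and
  dominant orientation φ₂; region summaries average I₂ per
  acquisition first, then across acquisitions.

* **Region statistics.** One-way ANOVA with Tukey–Kramer post hoc
  comparisons (studentized-range adjusted p, unequal group sizes
  supported) across NM/EM/LM, at per-pattern granularity for XRD and
  per-acquisition granularity for pSHG.

* **Synthetic data.** `generateScatterPattern()` /
  `generateScatterMap()` simulate scatter patterns (Porod background,
  meridional D-period orders, equatorial intermolecular arc, diffuse
  mineral lobe, beamstop, Poisson noise) and `generatePSHGStack()`
  simulates polarization stacks from the same harmonic model the
  fitter estimates, so every stage is testable against known ground
  truth without beamline or microscope data.

## Worked example

Reduce one synthetic non-mineralizing pattern:

```r
library(collagenHier)
geom   <- syntheticGeometry()          # 2000x2000 px, 75 um, 1250 mm
cache  <- reductionCache(geom)         # shared per-geometry indices
scenes <- regionScatterScenes()        # NM / EM / LM ground truth
pat <- generateScatterPattern(scenes$NM, geom, maps = cache$maps)
reducePattern(pat, geom, cache = cache)
#> XRDMetrics:
#>   d-period          66.939 nm
#>   intermol. spacing  2.370 nm
#>   fibril FWHM        31.29 deg
#>   molecular FWHM     37.53 deg
#>   raw twist           8.81 deg
#>   orientation        89.97 deg
```

The scene's ground truth is d-period 66.92 nm, spacing 2.37 nm,
fibril FWHM 31.19°, molecular FWHM 37.43°, twist σ 8.79° — every
metric is recovered within its documented tolerance (0.2 nm, 0.02 nm,
1°, 5%). Fit a shot-noise pSHG acquisition of the early-mineralizing
region (ground-truth I₂ = 0.29, a₀ = 500 counts):

```r
fit <- fitCircularHarmonics(generatePSHGStack(
    pshgRegionScene("EM", shape = c(256L, 256L))))
fit
#> PolarizationFit: 256 x 256 px, 65536 valid (100.0%)
#>   mean I2 = 0.2906, mean a0 = 500.1
```

Compare a metric across regions:

```r
cmp <- compareRegions(
    c(2.37, 2.38, 2.36, 2.16, 2.17, 2.15, 2.13, 2.14, 2.12),
    rep(c("NM", "EM", "LM"), each = 3),
    metric = "intermol_spacing_nm")
cmp$anova$f_statistic        # 513
as.data.frame(cmp$pairwise)[, c("group_1", "group_2", "q", "p_adj", "stars")]
#>   group_1 group_2         q        p_adj stars
#> 1      EM      LM  5.196152 2.422905e-02     *
#> 2      EM      NM 36.373067 7.597964e-07  ****
#> 3      LM      NM 41.569219 4.161494e-07  ****
```

`runPipeline(defaultRunConfig(seed = 1L))` chains all stages
(simulate → reduce/fit → compare) into CSV outputs plus a JSON
manifest; `inst/cli/collagen-tools.R` exposes the same stages as
shell subcommands (`simulate-xrd`, `simulate-pshg`, `reduce-xrd`,
`fit-pshg`, `compare-regions`, `run-demo`).

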