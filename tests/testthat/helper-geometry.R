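## Shared fixtures, built lazily and reused across test files.

.fixtures <- new.env(parent = emptyenv())

## Compact detector for cheap generator / integration unit tests:
## 256 x 256 px at a short camera length, on-axis Q up to ~4.1 nm^-1.
smallGeometry <- function() {
    detectorGeometry(sampleDetectorDistance = 150,
                     wavelength = 0.0979,
                     pixelPitch = 75,
                     detectorShape = c(256L, 256L),
                     beamCenter = c(128.5, 128.5),
                     beamstopRadius = 4)
}

smallMaps <- function() {
    if (is.null(.fixtures$smallMaps))
        .fixtures$smallMaps <- geometryMaps(smallGeometry())
    .fixtures$smallMaps
}

## Full synthetic-study geometry with its reduction cache (a few
## seconds to build; shared by round-trip and acceptance tests).
synthCache <- function() {
    if (is.null(.fixtures$synthCache))
        .fixtures$synthCache <- reductionCache(syntheticGeometry())
    .fixtures$synthCache
}

synthGeometry <- function() syntheticGeometry()

## Analytic radial profile I = amp * q^-4 (+ optional additive peak
## function) on a regular grid, for background-subtraction oracles.
analyticProfile <- function(qlo, qhi, n = 200, amp = 10,
                            peak = function(q) 0) {
    breaks <- seq(qlo, qhi, length.out = n + 1)
    centers <- (breaks[-1] + breaks[-(n + 1)]) / 2
    new("RadialProfile", q = centers,
        intensity = amp * centers^-4 + peak(centers),
        npix = rep(100L, n), azimuthWindow = list())
}
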