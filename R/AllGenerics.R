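## Accessor generics. Slot access outside the package goes through
## these, never through @.

#' @name accessors
#' @title Accessors for collagenHier result objects
#' @param object an object of the documented classes.
#' @description Small accessor generics: `dPeriod`, `intermolSpacing`,
#'   `fibrilFWHM`, `molecularFWHM`, `rawTwist`, `relativeTwist`,
#'   `preferredOrientation`, `qValues`, `netSignal`, `azimuthValues`,
#'   `signalValues`, `a0Map`, `i2Map`, `phi2Map`, `i4Map`, `phi4Map`,
#'   `validMask`, `stackAngles`, `patternList`, `scanPositions`.
NULL

#' @rdname accessors
#' @export
setGeneric("dPeriod", function(object) standardGeneric("dPeriod"))
#' @rdname accessors
#' @export
setGeneric("intermolSpacing",
    function(object) standardGeneric("intermolSpacing"))
#' @rdname accessors
#' @export
setGeneric("fibrilFWHM", function(object) standardGeneric("fibrilFWHM"))
#' @rdname accessors
#' @export
setGeneric("molecularFWHM",
    function(object) standardGeneric("molecularFWHM"))
#' @rdname accessors
#' @export
setGeneric("rawTwist", function(object) standardGeneric("rawTwist"))
#' @rdname accessors
#' @export
setGeneric("relativeTwist", function(object) standardGeneric("relativeTwist"))
#' @rdname accessors
#' @export
setGeneric("preferredOrientation",
    function(object) standardGeneric("preferredOrientation"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("netSignal", function(object) standardGeneric("netSignal"))
#' @rdname accessors
#' @export
setGeneric("azimuthValues", function(object) standardGeneric("azimuthValues"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("a0Map", function(object) standardGeneric("a0Map"))
#' @rdname accessors
#' @export
setGeneric("i2Map", function(object) standardGeneric("i2Map"))
#' @rdname accessors
#' @export
setGeneric("phi2Map", function(object) standardGeneric("phi2Map"))
#' @rdname accessors
#' @export
setGeneric("i4Map", function(object) standardGeneric("i4Map"))
#' @rdname accessors
#' @export
setGeneric("phi4Map", function(object) standardGeneric("phi4Map"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("stackAngles", function(object) standardGeneric("stackAngles"))
#' @rdname accessors
#' @export
setGeneric("patternList", function(object) standardGeneric("patternList"))
#' @rdname accessors
#' @export
setGeneric("scanPositions", function(object) standardGeneric("scanPositions"))

setMethod("dPeriod", "XRDMetrics", function(object) object@dPeriod)
setMethod("intermolSpacing", "XRDMetrics",
    function(object) object@intermolSpacing)
setMethod("fibrilFWHM", "XRDMetrics", function(object) object@fibrilFWHM)
setMethod("molecularFWHM", "XRDMetrics",
    function(object) object@molecularFWHM)
setMethod("rawTwist", "XRDMetrics", function(object) object@rawTwist)
setMethod("relativeTwist", "XRDMetrics",
    function(object) object@relativeTwist)
setMethod("preferredOrientation", "XRDMetrics",
    function(object) object@preferredOrientation)

setMethod("qValues", "RadialProfile", function(object) object@q)
setMethod("qValues", "PorodResult", function(object) object@q)
setMethod("qValues", "PeakFit", function(object) object@centerQ)
setMethod("netSignal", "PorodResult", function(object) object@net)

setMethod("azimuthValues", "AzimuthalProfile", function(object) object@azimuth)
setMethod("signalValues", "AzimuthalProfile", function(object) object@signal)

setMethod("a0Map", "PolarizationFit", function(object) object@a0Map)
setMethod("i2Map", "PolarizationFit", function(object) object@i2Map)
setMethod("phi2Map", "PolarizationFit", function(object) object@phi2Map)
setMethod("i4Map", "PolarizationFit", function(object) object@i4Map)
setMethod("phi4Map", "PolarizationFit", function(object) object@phi4Map)
setMethod("validMask", "PolarizationFit", function(object) object@mask)
setMethod("stackAngles", "PSHGStack", function(object) object@angles)
setMethod("stackAngles", "PSHGScene", function(object) object@angles)

setMethod("patternList", "ScatterMap", function(object) object@patterns)
setMethod("scanPositions", "ScatterMap", function(object) object@positions)

## ---- show methods -------------------------------------------------

#' @exportMethod show
setMethod("show", "DetectorGeometry", function(object) {
    cat("DetectorGeometry:",
        sprintf("%d x %d px, pitch %.1f um", object@detectorShape[1],
                object@detectorShape[2], object@pixelPitch), "\n")
    cat(sprintf("  L = %.0f mm, lambda = %.4f nm, beamstop %.0f px\n",
                object@sampleDetectorDistance, object@wavelength,
                object@beamstopRadius))
    cat(sprintf("  beam center (x, y) = (%.1f, %.1f)\n",
                object@beamCenter[1], object@beamCenter[2]))
})

setMethod("show", "ScatterScene", function(object) {
    cat("ScatterScene:\n")
    cat(sprintf("  d-period %.2f nm, intermolecular spacing %.3f nm\n",
                object@dPeriod, object@intermolSpacing))
    cat(sprintf("  fibril sigma %.2f deg, twist sigma %.2f deg, orientation %.1f deg\n",
                object@fibrilSigma, object@twistSigma,
                object@preferredOrientation))
    cat(sprintf("  porod %.3g, mineral fraction %.2f, noise %s (seed %d)\n",
                object@porodAmplitude, object@mineralFraction,
                if (object@poissonNoise) "poisson" else "off", object@seed))
})

setMethod("show", "ScatterMap", function(object) {
    cat(sprintf("ScatterMap: %d patterns (%s regions)\n",
                length(object@patterns),
                paste(unique(object@positions$region), collapse = "/")))
})

setMethod("show", "RadialProfile", function(object) {
    cat(sprintf("RadialProfile: %d bins, Q [%.3f, %.3f] nm^-1\n",
                length(object@q), min(object@q), max(object@q)))
})

setMethod("show", "AzimuthalProfile", function(object) {
    cat(sprintf("AzimuthalProfile: 720 x 0.5 deg segments, %d missing\n",
                sum(object@missing)))
})

setMethod("show", "PeakFit", function(object) {
    cat(sprintf("PeakFit (%s): center %.4f nm^-1 (d = %.3f nm)\n",
                object@method, object@centerQ, 2 * pi / object@centerQ))
})

setMethod("show", "XRDMetrics", function(object) {
    cat("XRDMetrics:\n")
    cat(sprintf("  d-period        %8.3f nm\n", object@dPeriod))
    cat(sprintf("  intermol. spacing %6.3f nm\n", object@intermolSpacing))
    cat(sprintf("  fibril FWHM     %8.2f deg\n", object@fibrilFWHM))
    cat(sprintf("  molecular FWHM  %8.2f deg\n", object@molecularFWHM))
    cat(sprintf("  raw twist       %8.2f deg\n", object@rawTwist))
    cat(sprintf("  orientation     %8.2f deg\n", object@preferredOrientation))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "PSHGScene", function(object) {
    d <- dim(object@a0Field)
    cat(sprintf("PSHGScene: %d x %d px, %d angles, shot noise %s (seed %d)\n",
                d[1], d[2], length(object@angles),
                if (object@shotNoise) "on" else "off", object@seed))
})

setMethod("show", "PSHGStack", function(object) {
    d <- dim(object@intensities)
    cat(sprintf("PSHGStack: %d x %d x %d, angles %s deg, pixel %.3f um\n",
                d[1], d[2], d[3],
                paste(range(object@angles), collapse = ".."),
                object@pixelSize))
})

setMethod("show", "PolarizationFit", function(object) {
    d <- dim(object@a0Map)
    ok <- object@mask
    cat(sprintf("PolarizationFit: %d x %d px, %d valid (%.1f%%)\n",
                d[1], d[2], sum(ok), 100 * mean(ok)))
    if (any(ok))
        cat(sprintf("  mean I2 = %.4f, mean a0 = %.1f\n",
                    mean(object@i2Map[ok]), mean(object@a0Map[ok])))
})

setMethod("show", "ReductionConfig", function(object) {
    cat("ReductionConfig:\n")
    cat(sprintf("  D-period window [%.2f, %.2f], intermolecular [%.2f, %.2f] nm^-1\n",
                object@dPeriodWindow[1], object@dPeriodWindow[2],
                object@intermolWindow[1], object@intermolWindow[2]))
    cat(sprintf("  %d segments, wedge +/-%.0f deg, porod method '%s'\n",
                object@nSegments, object@wedgeHalfWidth, object@porodMethod))
})
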