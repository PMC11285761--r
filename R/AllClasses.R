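## S4 classes for the two modalities. Conventions used everywhere:
##   * lengths: nm (wavelength, spacings), mm (sample-detector distance),
##     um (pixel pitch);
##   * angles: degrees; detector azimuth counter-clockwise from +x in
##     [0, 360); orientations are fibre-symmetric, i.e. defined mod 180;
##   * wavevector Q in nm^-1 with Q = 2*pi/d;
##   * masked detector pixels are NA in memory, sentinel -1 on disk.

#' DetectorGeometry: pixel-to-wavevector mapping
#'
#' Describes a small-angle scattering detector: sample-detector distance,
#' wavelength, pixel pitch, beam center, detector shape and a circular
#' beamstop. Defaults follow an Eiger2 4M-class setup (700 mm camera
#' length, 0.0979 nm wavelength, 75 um pixels, 2162 x 2068 pixels).
#'
#' @slot sampleDetectorDistance numeric, mm.
#' @slot wavelength numeric, nm.
#' @slot pixelPitch numeric, um.
#' @slot beamCenter numeric(2), (x, y) in pixel units (x along columns,
#'   y along rows).
#' @slot detectorShape integer(2), (rows, cols).
#' @slot beamstopRadius numeric, pixels; pixels closer to the beam
#'   center are treated as masked.
#' @name DetectorGeometry-class
#' @aliases DetectorGeometry-class
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
    representation(
        sampleDetectorDistance = "numeric",
        wavelength = "numeric",
        pixelPitch = "numeric",
        beamCenter = "numeric",
        detectorShape = "integer",
        beamstopRadius = "numeric"
    )
)

setValidity("DetectorGeometry", function(object) {
    msg <- character()
    if (length(object@sampleDetectorDistance) != 1 ||
        object@sampleDetectorDistance <= 0)
        msg <- c(msg, "sampleDetectorDistance must be a positive scalar (mm)")
    if (length(object@wavelength) != 1 || object@wavelength <= 0)
        msg <- c(msg, "wavelength must be a positive scalar (nm)")
    if (length(object@pixelPitch) != 1 || object@pixelPitch <= 0)
        msg <- c(msg, "pixelPitch must be a positive scalar (um)")
    if (length(object@detectorShape) != 2 || any(object@detectorShape < 1))
        msg <- c(msg, "detectorShape must be two positive integers (rows, cols)")
    if (length(object@beamCenter) != 2)
        msg <- c(msg, "beamCenter must be (x, y)")
    else if (length(object@detectorShape) == 2 &&
             (object@beamCenter[1] < 1 ||
              object@beamCenter[1] > object@detectorShape[2] ||
              object@beamCenter[2] < 1 ||
              object@beamCenter[2] > object@detectorShape[1]))
        msg <- c(msg, "beamCenter must lie inside the detector")
    if (length(object@beamstopRadius) != 1 || object@beamstopRadius < 0)
        msg <- c(msg, "beamstopRadius must be a non-negative scalar (pixels)")
    if (length(msg)) msg else TRUE
})

#' ScatterScene: ground truth for one synthetic scatter pattern
#'
#' Real-space and intensity parameters from which a fiber-diffraction
#' pattern is simulated: collagen D-period and its meridional orders,
#' intermolecular spacing, azimuthal dispersions of fibrils and
#' (intrafibrillar) molecular twist, a Porod background and a diffuse
#' low-Q mineral lobe.
#'
#' @slot dPeriod numeric, nm; axial gap-overlap repeat (~67 nm).
#' @slot intermolSpacing numeric, nm; lateral molecular spacing (~2.3 nm).
#' @slot fibrilSigma numeric, deg; azimuthal std of fibril orientations.
#' @slot twistSigma numeric, deg; intrafibrillar molecular spread; the
#'   equatorial arc carries quadrature spread sqrt(fibrilSigma^2 +
#'   twistSigma^2).
#' @slot preferredOrientation numeric, deg; fibril axis azimuth (mod 180).
#' @slot porodAmplitude numeric; scale c of the c*Q^-4 background.
#' @slot mineralFraction numeric >= 0; scales the diffuse mineral lobe.
#' @slot dPeriodAmplitudes numeric(3); peak amplitudes of meridional
#'   orders 1-3.
#' @slot intermolAmplitude numeric; amplitude of the equatorial arc.
#' @slot poissonNoise logical; Poisson-sample the clean image.
#' @slot seed integer; seed for all randomness of this scene.
#' @name ScatterScene-class
#' @exportClass ScatterScene
setClass("ScatterScene",
    representation(
        dPeriod = "numeric",
        intermolSpacing = "numeric",
        fibrilSigma = "numeric",
        twistSigma = "numeric",
        preferredOrientation = "numeric",
        porodAmplitude = "numeric",
        mineralFraction = "numeric",
        dPeriodAmplitudes = "numeric",
        intermolAmplitude = "numeric",
        poissonNoise = "logical",
        seed = "integer"
    )
)

setValidity("ScatterScene", function(object) {
    msg <- character()
    if (object@dPeriod <= 0) msg <- c(msg, "dPeriod must be > 0")
    if (object@intermolSpacing <= 0)
        msg <- c(msg, "intermolSpacing must be > 0")
    if (object@fibrilSigma < 0) msg <- c(msg, "fibrilSigma must be >= 0")
    if (object@twistSigma < 0) msg <- c(msg, "twistSigma must be >= 0")
    if (object@mineralFraction < 0)
        msg <- c(msg, "mineralFraction must be >= 0")
    if (length(object@dPeriodAmplitudes) != 3 ||
        any(object@dPeriodAmplitudes < 0))
        msg <- c(msg, "dPeriodAmplitudes must be 3 non-negative values")
    if (object@intermolAmplitude < 0)
        msg <- c(msg, "intermolAmplitude must be >= 0")
    if (object@porodAmplitude < 0)
        msg <- c(msg, "porodAmplitude must be >= 0")
    if (length(msg)) msg else TRUE
})

#' RegionLayout: raster of region labels with per-region scenes
#'
#' @slot labels character matrix; each cell one of the names of
#'   `scenes` (canonically "NM", "EM", "LM").
#' @slot scenes named list of [ScatterScene-class] objects.
#' @slot pitch numeric(2); scan pitch (x, y) in um.
#' @name RegionLayout-class
#' @exportClass RegionLayout
setClass("RegionLayout",
    representation(labels = "matrix", scenes = "list", pitch = "numeric")
)

setValidity("RegionLayout", function(object) {
    msg <- character()
    if (!is.character(object@labels) || length(object@labels) == 0)
        msg <- c(msg, "labels must be a non-empty character matrix")
    if (is.null(names(object@scenes)) ||
        !all(object@labels %in% names(object@scenes)))
        msg <- c(msg, "every label must name an entry of scenes")
    if (!all(vapply(object@scenes, is, logical(1), "ScatterScene")))
        msg <- c(msg, "scenes must all be ScatterScene objects")
    if (length(object@pitch) != 2 || any(object@pitch <= 0))
        msg <- c(msg, "pitch must be two positive values (um)")
    if (length(msg)) msg else TRUE
})

#' ScatterMap: an ordered collection of scatter patterns
#'
#' Patterns are stored in serpentine (snake-scan) acquisition order; the
#' positions table carries the raster indices and stage coordinates.
#'
#' @slot patterns list of numeric matrices (masked pixels NA).
#' @slot positions data.frame with columns index, row, col, x_um, y_um,
#'   region.
#' @slot geometry [DetectorGeometry-class].
#' @name ScatterMap-class
#' @exportClass ScatterMap
setClass("ScatterMap",
    representation(
        patterns = "list",
        positions = "data.frame",
        geometry = "DetectorGeometry"
    )
)

setValidity("ScatterMap", function(object) {
    msg <- character()
    if (nrow(object@positions) != length(object@patterns))
        msg <- c(msg, "positions must have one row per pattern")
    need <- c("index", "row", "col", "x_um", "y_um", "region")
    if (!all(need %in% names(object@positions)))
        msg <- c(msg, paste("positions needs columns:",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' RadialProfile: azimuthally integrated intensity versus Q
#'
#' @slot q numeric; bin centers, nm^-1, strictly increasing.
#' @slot intensity numeric; mean intensity per bin (NA where empty).
#' @slot npix integer; unmasked pixels per bin.
#' @slot azimuthWindow list of numeric(2) azimuth intervals (deg).
#' @name RadialProfile-class
#' @exportClass RadialProfile
setClass("RadialProfile",
    representation(
        q = "numeric",
        intensity = "numeric",
        npix = "integer",
        azimuthWindow = "list"
    )
)

setValidity("RadialProfile", function(object) {
    msg <- character()
    if (length(object@q) < 2 || any(diff(object@q) <= 0))
        msg <- c(msg, "q must be strictly increasing")
    if (length(object@intensity) != length(object@q))
        msg <- c(msg, "intensity must align with q")
    if (length(object@npix) != length(object@q))
        msg <- c(msg, "npix must align with q")
    if (length(msg)) msg else TRUE
})

#' PorodResult: background-subtracted peak region of a radial profile
#'
#' Produced by [porodSubtract()]. With `method = "log"` (the default)
#' the net signal is the exponentiated log-residual minus one,
#' I/I_fit - 1, dimensionless and ~0 on pure background; with
#' `method = "linear"` it is I - I_fit in intensity units.
#'
#' @slot q numeric; bin centers inside the peak window.
#' @slot net numeric; net peak signal per bin.
#' @slot intensity numeric; raw intensity per bin.
#' @slot fit numeric(2); (intercept, slope) of the ln I ~ ln Q line.
#' @slot method character; "log" or "linear".
#' @slot peakWindow numeric(2).
#' @slot flankWindows list of two numeric(2).
#' @name PorodResult-class
#' @exportClass PorodResult
setClass("PorodResult",
    representation(
        q = "numeric",
        net = "numeric",
        intensity = "numeric",
        fit = "numeric",
        method = "character",
        peakWindow = "numeric",
        flankWindows = "list"
    )
)

#' AzimuthalProfile: per-segment background-subtracted peak signal
#'
#' 720 azimuthal segments of 0.5 degrees; the signal is the total net
#' peak signal of the configured Q window in each segment.
#'
#' @slot azimuth numeric(720); segment centers, deg.
#' @slot signal numeric(720); net peak signal (NA where missing).
#' @slot missing logical(720); segments whose flank fit was undetermined.
#' @name AzimuthalProfile-class
#' @exportClass AzimuthalProfile
setClass("AzimuthalProfile",
    representation(
        azimuth = "numeric",
        signal = "numeric",
        missing = "logical"
    )
)

setValidity("AzimuthalProfile", function(object) {
    msg <- character()
    if (length(object@azimuth) != 720)
        msg <- c(msg, "exactly 720 azimuthal bins are required")
    else if (max(abs(diff(object@azimuth) - 0.5)) > 1e-9)
        msg <- c(msg, "azimuthal bin pitch must be 0.5 deg")
    if (length(object@signal) != length(object@azimuth))
        msg <- c(msg, "signal must align with azimuth")
    if (length(object@missing) != length(object@azimuth))
        msg <- c(msg, "missing must align with azimuth")
    if (length(msg)) msg else TRUE
})

#' PeakFit: summary of one radial diffraction peak
#'
#' @slot centerQ numeric, nm^-1.
#' @slot width numeric, nm^-1 (Gaussian sigma; NA for centroid method).
#' @slot area numeric; integrated net signal.
#' @slot method character; "gaussian" or "centroid".
#' @name PeakFit-class
#' @exportClass PeakFit
setClass("PeakFit",
    representation(
        centerQ = "numeric",
        width = "numeric",
        area = "numeric",
        method = "character"
    )
)

setValidity("PeakFit", function(object) {
    msg <- character()
    if (!object@method %in% c("gaussian", "centroid"))
        msg <- c(msg, "method must be 'gaussian' or 'centroid'")
    if (object@method == "gaussian" && is.finite(object@width) &&
        object@width <= 0)
        msg <- c(msg, "width must be > 0 for the gaussian method")
    if (length(msg)) msg else TRUE
})

#' XRDMetrics: the five structural metrics of one scatter pattern
#'
#' @slot dPeriod numeric, nm (NA when missing).
#' @slot intermolSpacing numeric, nm.
#' @slot fibrilFWHM numeric, deg; azimuthal FWHM of the D-period arc.
#' @slot molecularFWHM numeric, deg; azimuthal FWHM of the equatorial arc.
#' @slot rawTwist numeric, deg; quadrature excess of molecular over
#'   fibril dispersion (Gaussian-sigma units).
#' @slot relativeTwist numeric; rawTwist normalized by the mean NM raw
#'   twist (NA until normalized at map level).
#' @slot preferredOrientation numeric, deg in [0, 180).
#' @slot flags character; accumulated quality flags.
#' @name XRDMetrics-class
#' @exportClass XRDMetrics
setClass("XRDMetrics",
    representation(
        dPeriod = "numeric",
        intermolSpacing = "numeric",
        fibrilFWHM = "numeric",
        molecularFWHM = "numeric",
        rawTwist = "numeric",
        relativeTwist = "numeric",
        preferredOrientation = "numeric",
        flags = "character"
    )
)

#' PSHGScene: ground truth for one synthetic pSHG acquisition
#'
#' Per-pixel parameter fields of the circular-harmonic polarization
#' response I(alpha) = a0 * (1 + i2 cos 2(alpha - phi2)
#' + i4 cos 4(alpha - phi4)).
#'
#' @slot a0Field numeric matrix; mean intensity (counts).
#' @slot i2Field numeric matrix in [0, 1].
#' @slot phi2Field numeric matrix, deg in [0, 180).
#' @slot i4Field numeric matrix >= 0.
#' @slot phi4Field numeric matrix, deg in [0, 90).
#' @slot angles numeric; polarization angles, deg, strictly increasing.
#' @slot shotNoise logical.
#' @slot seed integer.
#' @name PSHGScene-class
#' @exportClass PSHGScene
setClass("PSHGScene",
    representation(
        a0Field = "matrix",
        i2Field = "matrix",
        phi2Field = "matrix",
        i4Field = "matrix",
        phi4Field = "matrix",
        angles = "numeric",
        shotNoise = "logical",
        seed = "integer"
    )
)

setValidity("PSHGScene", function(object) {
    msg <- character()
    dm <- dim(object@a0Field)
    for (s in c("i2Field", "phi2Field", "i4Field", "phi4Field"))
        if (!identical(dim(slot(object, s)), dm))
            msg <- c(msg, "all parameter fields must share one raster shape")
    if (any(object@i2Field < 0)) msg <- c(msg, "i2Field must be >= 0")
    if (any(object@i4Field < 0)) msg <- c(msg, "i4Field must be >= 0")
    if (length(object@angles) < 2 || any(diff(object@angles) <= 0))
        msg <- c(msg, "angles must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' PSHGStack: a polarization-resolved SHG image stack
#'
#' @slot intensities numeric array (rows, cols, n_angles).
#' @slot angles numeric; polarization angles, deg.
#' @slot pixelSize numeric, um (default 384.5/512).
#' @name PSHGStack-class
#' @exportClass PSHGStack
setClass("PSHGStack",
    representation(
        intensities = "array",
        angles = "numeric",
        pixelSize = "numeric"
    )
)

setValidity("PSHGStack", function(object) {
    msg <- character()
    d <- dim(object@intensities)
    if (length(d) != 3)
        msg <- c(msg, "intensities must be a 3D array (rows, cols, angles)")
    else if (d[3] != length(object@angles))
        msg <- c(msg, sprintf("array has %d pages but %d angles", d[3],
                              length(object@angles)))
    if (length(object@angles) < 5)
        msg <- c(msg, "at least 5 angles are required (five model parameters)")
    if (anyDuplicated(round(object@angles %% 180, 9)))
        msg <- c(msg, "angles must be distinct modulo 180 deg")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (length(msg)) msg else TRUE
})

#' PolarizationFit: per-pixel circular-harmonic fit of a pSHG stack
#'
#' @slot a0Map numeric matrix; mean intensity.
#' @slot i2Map numeric matrix; 2-alpha amplitude normalized by a0.
#' @slot phi2Map numeric matrix, deg in [0, 180).
#' @slot i4Map numeric matrix; 4-alpha amplitude normalized by a0.
#' @slot phi4Map numeric matrix, deg in [0, 90).
#' @slot amp2Map numeric matrix; unnormalized 2-alpha amplitude.
#' @slot residualMap numeric matrix; RMS fit residual.
#' @slot mask logical matrix; TRUE where the pixel is valid.
#' @name PolarizationFit-class
#' @exportClass PolarizationFit
setClass("PolarizationFit",
    representation(
        a0Map = "matrix",
        i2Map = "matrix",
        phi2Map = "matrix",
        i4Map = "matrix",
        phi4Map = "matrix",
        amp2Map = "matrix",
        residualMap = "matrix",
        mask = "matrix"
    )
)

setValidity("PolarizationFit", function(object) {
    msg <- character()
    dm <- dim(object@a0Map)
    for (s in c("i2Map", "phi2Map", "i4Map", "phi4Map", "amp2Map",
                "residualMap", "mask"))
        if (!identical(dim(slot(object, s)), dm))
            msg <- c(msg, "all maps must share one raster shape")
    ok <- object@mask
    if (any(object@i2Map[ok] < 0, na.rm = TRUE) ||
        any(object@i4Map[ok] < 0, na.rm = TRUE))
        msg <- c(msg, "i2/i4 must be >= 0 on unmasked pixels")
    if (length(msg)) msg else TRUE
})

#' ReductionConfig: windows and tuning of the XRD reduction
#'
#' Defaults follow the analysis windows of the method: D-period
#' (third meridional order) 0.24-0.32 nm^-1, intermolecular
#' 1.9-3.5 nm^-1, usable range 0.2-5 nm^-1, 720 azimuthal segments of
#' 0.5 deg, and a +/-20 deg wedge about the preferred orientation for
#' radial profiles.
#'
#' @slot dPeriodWindow numeric(2), nm^-1.
#' @slot intermolWindow numeric(2), nm^-1.
#' @slot usableQ numeric(2), nm^-1.
#' @slot flankFraction numeric; flank width as a fraction of the peak
#'   window width for full-wedge radial profiles.
#' @slot azFlankFractionD numeric; flank fraction for the per-segment
#'   azimuthal stage on the D-period window (wider, so that 0.5 deg
#'   segments keep >= 3 usable flank bins).
#' @slot azFlankFractionIM numeric; same for the intermolecular window.
#' @slot nSegments integer; azimuthal segments (720).
#' @slot wedgeHalfWidth numeric, deg.
#' @slot minCounts numeric; per-pattern minimum total counts gate.
#' @slot porodMethod character; "log" (exponentiated log residual) or
#'   "linear" (subtract exp(fit)).
#' @name ReductionConfig-class
#' @exportClass ReductionConfig
setClass("ReductionConfig",
    representation(
        dPeriodWindow = "numeric",
        intermolWindow = "numeric",
        usableQ = "numeric",
        flankFraction = "numeric",
        azFlankFractionD = "numeric",
        azFlankFractionIM = "numeric",
        nSegments = "integer",
        wedgeHalfWidth = "numeric",
        minCounts = "numeric",
        porodMethod = "character"
    )
)

setValidity("ReductionConfig", function(object) {
    msg <- character()
    w1 <- object@dPeriodWindow; w2 <- object@intermolWindow
    u <- object@usableQ
    if (length(w1) != 2 || w1[1] >= w1[2])
        msg <- c(msg, "dPeriodWindow must be an increasing interval")
    if (length(w2) != 2 || w2[1] >= w2[2])
        msg <- c(msg, "intermolWindow must be an increasing interval")
    if (length(u) != 2 || u[1] >= u[2])
        msg <- c(msg, "usableQ must be an increasing interval")
    if (length(w1) == 2 && length(w2) == 2 && w1[2] > w2[1])
        msg <- c(msg, "peak windows must not overlap")
    if (length(w1) == 2 && length(u) == 2 &&
        (w1[1] < u[1] || w2[2] > u[2]))
        msg <- c(msg, "peak windows must lie inside the usable Q range")
    if (object@nSegments != 720L)
        msg <- c(msg, "the azimuthal stage uses exactly 720 segments")
    if (!object@porodMethod %in% c("log", "linear"))
        msg <- c(msg, "porodMethod must be 'log' or 'linear'")
    if (length(msg)) msg else TRUE
})
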