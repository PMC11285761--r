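#' Construct a detector geometry
#'
#' @param sampleDetectorDistance camera length, mm.
#' @param wavelength X-ray wavelength, nm (0.0979 nm = 12.66 keV).
#' @param pixelPitch pixel pitch, um.
#' @param detectorShape integer(2), (rows, cols).
#' @param beamCenter numeric(2), (x, y) in pixels; defaults to the
#'   detector center.
#' @param beamstopRadius beamstop radius, pixels.
#' @return A [DetectorGeometry-class] object.
#' @examples
#' detectorGeometry()            # Eiger2 4M-class defaults
#' syntheticGeometry()           # bundled synthetic-study geometry
#' @export
detectorGeometry <- function(sampleDetectorDistance = 700,
                             wavelength = 0.0979,
                             pixelPitch = 75,
                             detectorShape = c(2162L, 2068L),
                             beamCenter = NULL,
                             beamstopRadius = 20) {
    detectorShape <- as.integer(detectorShape)
    if (is.null(beamCenter))
        beamCenter <- c((detectorShape[2] + 1) / 2, (detectorShape[1] + 1) / 2)
    methods::new("DetectorGeometry",
        sampleDetectorDistance = sampleDetectorDistance,
        wavelength = wavelength,
        pixelPitch = pixelPitch,
        beamCenter = as.numeric(beamCenter),
        detectorShape = detectorShape,
        beamstopRadius = beamstopRadius)
}

#' @rdname detectorGeometry
#' @details `syntheticGeometry()` is the geometry used by the bundled
#'   simulations: 2000 x 2000 pixels of 75 um at 1250 mm, reaching
#'   Q = 3.85 nm^-1 on-axis (beyond 5 nm^-1 diagonally) with a beamstop
#'   below Q = 0.18 nm^-1. The longer camera length (versus the 700 mm
#'   default) spreads the narrow D-period window over enough pixels that
#'   every 0.5 deg azimuthal segment supports its own background fit.
#' @export
syntheticGeometry <- function() {
    detectorGeometry(sampleDetectorDistance = 1250,
                     wavelength = 0.0979,
                     pixelPitch = 75,
                     detectorShape = c(2000L, 2000L),
                     beamCenter = c(1000.5, 1000.5),
                     beamstopRadius = 45)
}

#' Map detector pixels to wavevector and azimuth
#'
#' Q = (4 pi / lambda) * sin(arctan(r / L) / 2) with r the in-plane
#' distance from the beam center and L the sample-detector distance.
#' Azimuth is measured counter-clockwise from the detector +x axis
#' (increasing column), in [0, 360). The beam-center pixel maps to
#' q = 0 with azimuth 0 by convention.
#'
#' @param geometry a [DetectorGeometry-class].
#' @param row,col pixel coordinates (1-based, vectorized, recycled).
#' @return A list with numeric vectors `q` (nm^-1) and `azimuth` (deg).
#' @examples
#' g <- detectorGeometry()
#' pixelToQ(g, g@beamCenter[2], g@beamCenter[1])$q  # 0 at the center
#' @export
pixelToQ <- function(geometry, row, col) {
    stopifnot(is(geometry, "DetectorGeometry"))
    ns <- geometry@detectorShape
    if (any(row < 1 | row > ns[1] | col < 1 | col > ns[2]))
        stop("pixel outside the detector")
    pitch_mm <- geometry@pixelPitch / 1000
    dx <- (col - geometry@beamCenter[1]) * pitch_mm
    dy <- (row - geometry@beamCenter[2]) * pitch_mm
    r <- sqrt(dx^2 + dy^2)
    q <- (4 * pi / geometry@wavelength) *
        sin(atan(r / geometry@sampleDetectorDistance) / 2)
    az <- (atan2(dy, dx) * 180 / pi) %% 360
    az[r == 0] <- 0
    list(q = q, azimuth = az)
}

#' Per-pixel Q/azimuth maps for a geometry
#'
#' Computes, once per geometry, the wavevector and azimuth of every
#' pixel plus the beamstop mask. Reduction functions accept the result
#' through their `maps` argument so it is shared across patterns.
#'
#' @param geometry a [DetectorGeometry-class].
#' @return list with matrices `q`, `azimuth` and logical `beamstop`
#'   (TRUE where occluded).
#' @export
geometryMaps <- function(geometry) {
    stopifnot(is(geometry, "DetectorGeometry"))
    ns <- geometry@detectorShape
    pitch_mm <- geometry@pixelPitch / 1000
    dx <- (seq_len(ns[2]) - geometry@beamCenter[1]) * pitch_mm
    dy <- (seq_len(ns[1]) - geometry@beamCenter[2]) * pitch_mm
    dxm <- matrix(dx, ns[1], ns[2], byrow = TRUE)
    dym <- matrix(dy, ns[1], ns[2])
    r <- sqrt(dxm^2 + dym^2)
    q <- (4 * pi / geometry@wavelength) *
        sin(atan(r / geometry@sampleDetectorDistance) / 2)
    az <- (atan2(dym, dxm) * 180 / pi) %% 360
    az[r == 0] <- 0
    bs <- r <= geometry@beamstopRadius * pitch_mm
    q4 <- q^-4
    q4[!is.finite(q4)] <- 0
    ## cacheEnv memoises deterministic intermediates (annulus indices,
    ## clean scene images) across the patterns of a scan
    list(q = q, azimuth = az, beamstop = bs, q4 = q4,
         cacheEnv = new.env(parent = emptyenv()))
}

## Largest Q guaranteed present at every azimuth (set by the nearest
## detector edge), and the Q below which the beamstop occludes.
geometryQLimits <- function(geometry) {
    ns <- geometry@detectorShape
    pitch_mm <- geometry@pixelPitch / 1000
    edge_px <- min(geometry@beamCenter[1] - 1,
                   ns[2] - geometry@beamCenter[1],
                   geometry@beamCenter[2] - 1,
                   ns[1] - geometry@beamCenter[2])
    qmax <- (4 * pi / geometry@wavelength) *
        sin(atan(edge_px * pitch_mm / geometry@sampleDetectorDistance) / 2)
    qmin <- (4 * pi / geometry@wavelength) *
        sin(atan(geometry@beamstopRadius * pitch_mm /
                 geometry@sampleDetectorDistance) / 2)
    c(qmin = qmin, qmax = qmax)
}
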