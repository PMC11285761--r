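## Synthetic fiber-diffraction scatter patterns with known ground
## truth. A pattern is the sum of
##   * a Porod background  c * Q^-4,
##   * meridional D-period arcs at Q = 2*pi*n/d (orders n = 1..3),
##     Gaussian in Q (sigma 0.01 nm^-1) and azimuth (sigma fibrilSigma)
##     about the preferred fibril orientation,
##   * an equatorial intermolecular arc at Q = 2*pi/spacing, Gaussian in
##     Q (sigma 0.25 nm^-1) with azimuthal spread
##     sqrt(fibrilSigma^2 + twistSigma^2) centered 90 deg away,
##   * a diffuse low-Q mineral lobe (Gaussian stand-in, see vignette)
##     on the equatorial azimuth, scaled by mineralFraction,
## optionally Poisson-sampled. Beamstop pixels are NA.

SIGMA_Q_D <- 0.01        # radial sigma of D-period orders, nm^-1
SIGMA_Q_IM <- 0.15       # radial sigma of the intermolecular arc,
                         # nm^-1; chosen so the arc (down to the
                         # smallest region spacing, q ~ 2.95 nm^-1)
                         # stays inside the 1.9-3.5 nm^-1 analysis
                         # window and clear of its background flanks
MINERAL_Q_CENTER <- 0.45 # mineral lobe center, nm^-1
MINERAL_Q_SIGMA <- 0.25  # mineral lobe radial sigma, nm^-1; decays to
                         # negligible well below the intermolecular
                         # flanks, while still overlapping the
                         # D-period window in Q
MINERAL_AZ_SIGMA <- 25   # mineral lobe azimuthal sigma, deg
MINERAL_SCALE <- 30      # mineral amplitude per unit mineralFraction,
                         # in units of porodAmplitude

#' Construct a synthetic scatter scene
#'
#' @param dPeriod collagen D-period, nm.
#' @param intermolSpacing lateral intermolecular spacing, nm.
#' @param fibrilSigma azimuthal std of fibril orientations, deg.
#' @param twistSigma intrafibrillar molecular spread, deg; the
#'   equatorial arc carries the quadrature sum of both sigmas.
#' @param preferredOrientation fibril axis azimuth, deg.
#' @param porodAmplitude scale of the Q^-4 background.
#' @param mineralFraction >= 0; scales the diffuse mineral lobe.
#' @param dPeriodAmplitudes numeric(3); meridional order amplitudes.
#' @param intermolAmplitude equatorial arc amplitude.
#' @param poissonNoise logical.
#' @param seed integer seed governing all randomness of the scene.
#' @return A [ScatterScene-class].
#' @export
scatterScene <- function(dPeriod = 67,
                         intermolSpacing = 2.33,
                         fibrilSigma = 10,
                         twistSigma = 8,
                         preferredOrientation = 90,
                         porodAmplitude = 10,
                         mineralFraction = 0,
                         dPeriodAmplitudes = c(800, 500, 5000),
                         intermolAmplitude = 2,
                         poissonNoise = FALSE,
                         seed = 1L) {
    methods::new("ScatterScene",
        dPeriod = dPeriod,
        intermolSpacing = intermolSpacing,
        fibrilSigma = fibrilSigma,
        twistSigma = twistSigma,
        preferredOrientation = preferredOrientation %% 180,
        porodAmplitude = porodAmplitude,
        mineralFraction = mineralFraction,
        dPeriodAmplitudes = dPeriodAmplitudes,
        intermolAmplitude = intermolAmplitude,
        poissonNoise = poissonNoise,
        seed = as.integer(seed))
}

#' Region scenes for the NM/EM/LM mineralization study
#'
#' Ground-truth parameters for the non-mineralizing (NM), early- (EM)
#' and late-mineralizing (LM) tendon regions: D-periods 66.92 / 67.46 /
#' 67.21 nm, spacings 2.37 / 2.16 / 2.13 nm, fibril dispersion FWHMs
#' 31.19 / 15.31 / 19.88 deg, twist sigmas 8.79 / 6.46 / 6.10 deg.
#'
#' @param poissonNoise logical; Poisson-sample the patterns.
#' @param exposure multiplies every intensity amplitude (use > 1 with
#'   noise so high-Q flanks keep adequate counts).
#' @param preferredOrientation fibril axis azimuth, deg.
#' @return Named list of [ScatterScene-class] objects (NM, EM, LM).
#' @export
regionScatterScenes <- function(poissonNoise = FALSE, exposure = 1,
                                preferredOrientation = 90) {
    fw <- FWHM_FACTOR
    mk <- function(d, spacing, fibFWHM, twistSigma, mineral, seed)
        scatterScene(dPeriod = d, intermolSpacing = spacing,
                     fibrilSigma = fibFWHM / fw, twistSigma = twistSigma,
                     preferredOrientation = preferredOrientation,
                     porodAmplitude = 10 * exposure,
                     mineralFraction = mineral,
                     dPeriodAmplitudes = c(800, 500, 5000) * exposure,
                     intermolAmplitude = 2 * exposure,
                     poissonNoise = poissonNoise, seed = seed)
    list(NM = mk(66.92, 2.37, 31.19, 8.79, 0.0, 101L),
         EM = mk(67.46, 2.16, 15.31, 6.46, 0.5, 102L),
         LM = mk(67.21, 2.13, 19.88, 6.10, 1.0, 103L))
}

#' Ground-truth reduction metrics implied by a scene
#'
#' @param scene a [ScatterScene-class].
#' @return Named numeric vector: dPeriod (nm), intermolSpacing (nm),
#'   fibrilFWHM (deg), molecularFWHM (deg), rawTwist (deg, sigma units).
#' @export
sceneMetrics <- function(scene) {
    stopifnot(is(scene, "ScatterScene"))
    sigMol <- sqrt(scene@fibrilSigma^2 + scene@twistSigma^2)
    c(dPeriod = scene@dPeriod,
      intermolSpacing = scene@intermolSpacing,
      fibrilFWHM = FWHM_FACTOR * scene@fibrilSigma,
      molecularFWHM = FWHM_FACTOR * sigMol,
      rawTwist = scene@twistSigma,
      preferredOrientation = scene@preferredOrientation)
}

## Azimuthal arc factor with 180-deg (Friedel) periodicity; sigma = 0
## collapses onto the 0.5-deg azimuthal bin containing the center.
azimuthalArcFactor <- function(az, center, sigma) {
    if (sigma == 0) {
        as.numeric(floor((az %% 180) / 0.5) ==
                   floor((center %% 180) / 0.5))
    } else {
        wrappedGaussian(az %% 180, center %% 180, sigma, period = 180)
    }
}

#' Generate one synthetic scatter pattern
#'
#' @param scene a [ScatterScene-class].
#' @param geometry a [DetectorGeometry-class]; must contain the
#'   intermolecular arc at every azimuth.
#' @param maps optional precomputed [geometryMaps()] result.
#' @param seed optional integer overriding `scene@seed` (used by the
#'   scan generator to give every position its own noise stream).
#' @return Numeric matrix of detector counts; beamstop pixels are NA
#'   (sentinel -1 when written to disk).
#' @examples
#' g <- syntheticGeometry()
#' sc <- scatterScene(poissonNoise = FALSE)
#' pat <- generateScatterPattern(sc, g)
#' @export
generateScatterPattern <- function(scene, geometry, maps = NULL,
                                   seed = NULL) {
    stopifnot(is(scene, "ScatterScene"), is(geometry, "DetectorGeometry"))
    if (is.null(maps)) maps <- geometryMaps(geometry)
    lim <- geometryQLimits(geometry)
    qT <- spacingToQ(scene@intermolSpacing)
    if (lim["qmax"] < qT + 2 * SIGMA_Q_IM)
        stop(sprintf(paste0("geometry too small to contain the ",
                            "intermolecular arc: covers Q <= %.2f nm^-1 at ",
                            "all azimuths but the arc extends to %.2f nm^-1"),
                     lim["qmax"], qT + 2 * SIGMA_Q_IM))
    img <- cleanScatterImage(scene, maps)
    if (scene@poissonNoise) {
        if (is.null(seed)) seed <- scene@seed
        img[] <- withSeed(seed, stats::rpois(length(img), img))
    }
    img[maps$beamstop] <- NA_real_
    img
}

## Noise-free scene intensity. Memoised per scene parameters on the
## maps cache environment: the patterns of a scan differ only in
## their noise draws, so the deterministic part is built once.
cleanScatterImage <- function(scene, maps) {
    key <- NULL
    if (!is.null(maps$cacheEnv)) {
        key <- paste0("scene|", paste(
            c(scene@dPeriod, scene@intermolSpacing, scene@fibrilSigma,
              scene@twistSigma, scene@preferredOrientation,
              scene@porodAmplitude, scene@mineralFraction,
              scene@dPeriodAmplitudes, scene@intermolAmplitude),
            collapse = "|"))
        hit <- maps$cacheEnv[[key]]
        if (!is.null(hit)) return(hit)
    }
    q <- maps$q
    az <- maps$azimuth
    qT <- spacingToQ(scene@intermolSpacing)
    ## Porod background (q4 is 0 at the beam-center pixel, which lies
    ## inside the beamstop)
    img <- scene@porodAmplitude * maps$q4
    po <- scene@preferredOrientation
    annulus <- function(lo, hi) {
        akey <- sprintf("annulus|%.6f|%.6f", lo, hi)
        if (!is.null(maps$cacheEnv)) {
            hit <- maps$cacheEnv[[akey]]
            if (!is.null(hit)) return(hit)
        }
        idx <- which(q > lo & q < hi)
        if (!is.null(maps$cacheEnv)) maps$cacheEnv[[akey]] <- idx
        idx
    }
    ## meridional D-period orders 1..3
    for (n in 1:3) {
        A <- scene@dPeriodAmplitudes[n]
        if (A <= 0) next
        qn <- n * spacingToQ(scene@dPeriod)
        idx <- annulus(qn - 6 * SIGMA_Q_D, qn + 6 * SIGMA_Q_D)
        if (!length(idx)) next
        img[idx] <- img[idx] +
            A * exp(-(q[idx] - qn)^2 / (2 * SIGMA_Q_D^2)) *
            azimuthalArcFactor(az[idx], po, scene@fibrilSigma)
    }
    ## equatorial intermolecular arc
    if (scene@intermolAmplitude > 0) {
        sigMol <- sqrt(scene@fibrilSigma^2 + scene@twistSigma^2)
        idx <- annulus(qT - 6 * SIGMA_Q_IM, qT + 6 * SIGMA_Q_IM)
        img[idx] <- img[idx] +
            scene@intermolAmplitude *
            exp(-(q[idx] - qT)^2 / (2 * SIGMA_Q_IM^2)) *
            azimuthalArcFactor(az[idx], po + 90, sigMol)
    }
    ## diffuse low-Q mineral lobe (documented Gaussian stand-in)
    if (scene@mineralFraction > 0) {
        Am <- scene@mineralFraction * scene@porodAmplitude * MINERAL_SCALE
        idx <- annulus(max(MINERAL_Q_CENTER - 6 * MINERAL_Q_SIGMA, 1e-9),
                       MINERAL_Q_CENTER + 6 * MINERAL_Q_SIGMA)
        img[idx] <- img[idx] +
            Am * exp(-(q[idx] - MINERAL_Q_CENTER)^2 /
                     (2 * MINERAL_Q_SIGMA^2)) *
            azimuthalArcFactor(az[idx], po + 90, MINERAL_AZ_SIGMA)
    }
    if (!is.null(key)) maps$cacheEnv[[key]] <- img
    img
}

#' Serpentine (snake-scan) position table
#'
#' Rows are visited top to bottom; odd rows scan left to right, even
#' rows right to left, matching a beamline snake scan.
#'
#' @param nRow,nCol raster dimensions.
#' @param pitch numeric(2); scan pitch (x, y) in um.
#' @return data.frame with columns index, row, col, x_um, y_um.
#' @export
serpentinePositions <- function(nRow, nCol, pitch = c(20, 100)) {
    rows <- rep(seq_len(nRow), each = nCol)
    cols <- unlist(lapply(seq_len(nRow), function(r)
        if (r %% 2 == 1) seq_len(nCol) else rev(seq_len(nCol))))
    data.frame(index = seq_len(nRow * nCol), row = rows, col = cols,
               x_um = (cols - 1) * pitch[1], y_um = (rows - 1) * pitch[2])
}

#' Build a banded NM/EM/LM region layout
#'
#' Splits the scan raster into three vertical bands (NM left, EM
#' middle, LM right), mirroring the distal-to-proximal progression of
#' mineralization along a tendon.
#'
#' @param nRow,nCol raster dimensions.
#' @param scenes named list of [ScatterScene-class] (defaults to
#'   [regionScatterScenes()]).
#' @param pitch scan pitch (x, y), um.
#' @return A [RegionLayout-class].
#' @export
regionBandLayout <- function(nRow, nCol,
                             scenes = regionScatterScenes(),
                             pitch = c(20, 100)) {
    bands <- cut(seq_len(nCol), breaks = 3, labels = names(scenes)[1:3])
    labels <- matrix(as.character(bands)[col(matrix(0, nRow, nCol))],
                     nRow, nCol)
    methods::new("RegionLayout", labels = labels, scenes = scenes,
                 pitch = as.numeric(pitch))
}

#' Generate a serpentine scan of scatter patterns
#'
#' One pattern per raster cell of the layout, in snake-scan order.
#' Deterministic: position i of a noisy scene draws from seed
#' `scene@seed + i`, so regenerating the map is bit-identical.
#'
#' @param layout a [RegionLayout-class].
#' @param geometry a [DetectorGeometry-class].
#' @param maps optional precomputed [geometryMaps()].
#' @return A [ScatterMap-class].
#' @export
generateScatterMap <- function(layout, geometry, maps = NULL) {
    stopifnot(is(layout, "RegionLayout"))
    methods::validObject(layout)
    if (is.null(maps)) maps <- geometryMaps(geometry)
    pos <- serpentinePositions(nrow(layout@labels), ncol(layout@labels),
                               layout@pitch)
    pos$region <- layout@labels[cbind(pos$row, pos$col)]
    patterns <- lapply(seq_len(nrow(pos)), function(i) {
        scene <- layout@scenes[[pos$region[i]]]
        generateScatterPattern(scene, geometry, maps = maps,
                               seed = scene@seed + pos$index[i])
    })
    methods::new("ScatterMap", patterns = patterns, positions = pos,
                 geometry = geometry)
}
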