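## Synthetic polarization-resolved SHG stacks. The forward model is the
## circular-harmonic response the analysis estimates:
##   I(alpha) = a0 * (1 + i2 cos 2(alpha - phi2) + i4 cos 4(alpha - phi4))
## clipped at zero, then Poisson-sampled when shot noise is on.

DEFAULT_PSHG_ANGLES <- seq(0, 165, by = 15)
DEFAULT_PSHG_PIXEL <- 384.5 / 512  # um; 384.5 um field over 512 px

#' Construct a synthetic pSHG scene
#'
#' Scalars are broadcast to the raster shape; matrices are used as-is.
#'
#' @param shape integer(2); raster shape (rows, cols), default 512 x 512.
#' @param a0 mean intensity per pixel (counts).
#' @param i2 normalized 2-alpha modulation in [0, 1].
#' @param phi2 dominant orientation, deg in [0, 180).
#' @param i4 normalized 4-alpha modulation >= 0.
#' @param phi4 4-alpha orientation, deg in [0, 90).
#' @param angles polarization angles, deg; default 0, 15, ..., 165
#'   (12 angles at 15 deg covering a 180 deg period).
#' @param shotNoise logical.
#' @param seed integer.
#' @return A [PSHGScene-class].
#' @export
pshgScene <- function(shape = c(512L, 512L), a0 = 500, i2 = 0.25,
                      phi2 = 45, i4 = 0.05, phi4 = 20,
                      angles = DEFAULT_PSHG_ANGLES,
                      shotNoise = TRUE, seed = 1L) {
    bc <- function(x) {
        if (is.matrix(x)) {
            stopifnot(identical(dim(x), as.integer(shape)))
            x
        } else matrix(x, shape[1], shape[2])
    }
    methods::new("PSHGScene",
        a0Field = bc(a0), i2Field = bc(i2),
        phi2Field = bc(phi2) %% 180, i4Field = bc(i4),
        phi4Field = bc(phi4) %% 90,
        angles = as.numeric(angles), shotNoise = shotNoise,
        seed = as.integer(seed))
}

#' Region pSHG scenes for the mineralization study
#'
#' Ground-truth organization parameters per region: mean I2 = 0.21 (NM),
#' 0.29 (EM), 0.33 (LM) at a0 = 500 counts. `i2Jitter` adds a
#' deterministic per-acquisition offset to the region I2 (drawn from a
#' normal with that standard deviation), emulating between-acquisition
#' variability for the statistics stage.
#'
#' @param region one of "NM", "EM", "LM".
#' @param acquisition integer acquisition number (seeds the jitter and
#'   the shot noise stream).
#' @param shape raster shape (rows, cols).
#' @param a0 mean intensity, counts.
#' @param shotNoise logical.
#' @param i2Jitter standard deviation of the per-acquisition I2 offset.
#' @return A [PSHGScene-class].
#' @export
pshgRegionScene <- function(region = c("NM", "EM", "LM"),
                            acquisition = 1L,
                            shape = c(512L, 512L),
                            a0 = 500, shotNoise = TRUE,
                            i2Jitter = 0) {
    region <- match.arg(region)
    base <- c(NM = 0.21, EM = 0.29, LM = 0.33)[[region]]
    phi <- c(NM = 60, EM = 90, LM = 120)[[region]]
    seed <- 1000L * match(region, c("NM", "EM", "LM")) +
        as.integer(acquisition)
    i2 <- base
    if (i2Jitter > 0)
        i2 <- max(0, base + withSeed(seed + 500000L,
                                     stats::rnorm(1, 0, i2Jitter)))
    pshgScene(shape = shape, a0 = a0, i2 = i2, phi2 = phi,
              i4 = 0.05, phi4 = 20, shotNoise = shotNoise, seed = seed)
}

#' Generate a pSHG stack from a scene
#'
#' Evaluates the circular-harmonic forward model per pixel and angle,
#' clips negative pre-noise intensities at zero (with a warning, since
#' i2 + i4 > 1 is unphysical for this parameterization) and applies
#' Poisson shot noise when requested.
#'
#' @param scene a [PSHGScene-class].
#' @return A [PSHGStack-class].
#' @examples
#' st <- generatePSHGStack(pshgScene(shape = c(32L, 32L),
#'                                   shotNoise = FALSE))
#' @export
generatePSHGStack <- function(scene) {
    stopifnot(is(scene, "PSHGScene"))
    methods::validObject(scene)
    ang <- scene@angles
    span <- diff(range(ang))
    step <- diff(ang)
    if (max(abs(step - step[1])) > 1e-9)
        stop("angles must be uniformly spaced")
    if (span + step[1] < 180 - 1e-9)
        stop("angles must cover at least a 180 deg period")
    d <- dim(scene@a0Field)
    n <- length(ang)
    stack <- array(0, dim = c(d[1], d[2], n))
    rad <- pi / 180
    clipped <- FALSE
    for (k in seq_len(n)) {
        a <- ang[k]
        img <- scene@a0Field *
            (1 + scene@i2Field * cos(2 * (a - scene@phi2Field) * rad) +
                 scene@i4Field * cos(4 * (a - scene@phi4Field) * rad))
        if (any(img < 0)) {
            clipped <- TRUE
            img[img < 0] <- 0
        }
        stack[, , k] <- img
    }
    if (clipped)
        warning("negative pre-noise intensities clipped to zero ",
                "(i2 + i4 > 1 somewhere in the scene)")
    if (scene@shotNoise)
        stack[] <- withSeed(scene@seed,
                            stats::rpois(length(stack), stack))
    methods::new("PSHGStack", intensities = stack, angles = ang,
                 pixelSize = DEFAULT_PSHG_PIXEL)
}
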