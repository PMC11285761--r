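#' @import methods
#' @importFrom stats rpois rnorm sd quantile aov pf ptukey approx ave
#' @importFrom utils combn packageVersion write.csv
NULL

## Shared numeric helpers. Angles are degrees throughout the package;
## wavevectors Q are nm^-1 with the convention Q = 2*pi/d.

## FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert wavevector to real-space spacing
#'
#' Uses the convention \eqn{d = 2\pi/Q}. The inverse is [spacingToQ()];
#' the pair round-trips to machine precision.
#'
#' @param q Wavevector magnitude(s), nm^-1.
#' @return Real-space spacing(s), nm.
#' @examples
#' qToSpacing(2.7)    # ~2.33 nm, the collagen intermolecular spacing
#' qToSpacing(0.28)   # ~22.4 nm, third order of the ~67 nm D-period
#' @export
qToSpacing <- function(q) {
    stopifnot(is.numeric(q))
    2 * pi / q
}

#' @rdname qToSpacing
#' @param d Real-space spacing(s), nm.
#' @export
spacingToQ <- function(d) {
    stopifnot(is.numeric(d))
    2 * pi / d
}

#' Photon energy to wavelength
#'
#' @param energy_eV Photon energy in electron volts.
#' @return Wavelength in nm (multiply by 10 for Angstrom).
#' @examples
#' energyToWavelength(12658) * 10  # ~0.979 Angstrom
#' @export
energyToWavelength <- function(energy_eV) {
    stopifnot(is.numeric(energy_eV), all(energy_eV > 0))
    ## hc = 1239.8419843320026 eV nm
    1239.8419843320026 / energy_eV
}

## Wrap an angular difference into (-period/2, period/2].
wrapAngle <- function(x, period = 180) {
    y <- x %% period
    y - period * (y > period / 2)
}

## Wrapped Gaussian density (unnormalized, peak 1) with period 180 deg.
## The principal wrapped distance term is exact to ~1e-9 for
## sigma <= 15; wider lobes add the neighboring wraps.
wrappedGaussian <- function(theta, center, sigma, period = 180) {
    if (sigma <= 0) stop("sigma must be > 0 for wrappedGaussian()")
    d <- wrapAngle(theta - center, period)
    out <- exp(-d^2 / (2 * sigma^2))
    if (sigma > 15) {
        out <- out + exp(-(d - period)^2 / (2 * sigma^2)) +
            exp(-(d + period)^2 / (2 * sigma^2))
        if (sigma > 45)
            out <- out + exp(-(d - 2 * period)^2 / (2 * sigma^2)) +
                exp(-(d + 2 * period)^2 / (2 * sigma^2))
    }
    out
}

## Evaluate code under a fixed RNG seed without disturbing global state.
withSeed <- function(seed, code) {
    withr::with_seed(as.integer(seed), code)
}

## Closed-form simple linear regression used by the Porod background
## fit; returns c(intercept, slope). Inputs must be finite.
linfitCore <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    sxx <- sum(x * x); sxy <- sum(x * y)
    den <- n * sxx - sx * sx
    if (den <= 0) stop("degenerate abscissa in linear fit")
    b <- (n * sxy - sx * sy) / den
    a <- (sy - b * sx) / n
    c(a, b)
}
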