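## Reduction of 2D scatter patterns to the five structural metrics:
## D-period, intermolecular spacing, fibril and molecular azimuthal
## dispersion FWHMs, and relative supramolecular twist.
##
## Peak metrics (centroid, Gaussian center) are always extracted on the
## intensity scale I - I_fit. With porodMethod = "log" the stored net
## signal is the exponentiated log residual I/I_fit - 1 (the literal
## background-subtraction sequence); multiplying back by the fitted
## background recovers I - I_fit exactly, and avoids the Q^4 Jacobian
## of the ratio residual displacing peak centers.

## q-bin widths of the full-wedge radial profiles (nm^-1)
RADIAL_BIN_D <- 0.002
RADIAL_BIN_IM <- 0.02
## q bins of the per-segment azimuthal stage (counts per zone)
AZ_PEAK_BINS_D <- 8L
AZ_FLANK_BINS_D <- 4L
AZ_PEAK_BINS_IM <- 16L
AZ_FLANK_BINS_IM <- 6L

#' Construct a reduction configuration
#'
#' @param dPeriodWindow Q window of the third meridional D-period
#'   order, nm^-1.
#' @param intermolWindow Q window of the intermolecular peak, nm^-1.
#' @param usableQ usable wavevector range, nm^-1.
#' @param flankFraction background flank width as a fraction of the
#'   peak-window width (full-wedge radial profiles).
#' @param azFlankFractionD,azFlankFractionIM flank fractions of the
#'   720-segment azimuthal stage for the two windows. The D-period
#'   default is wider (0.5) so each 0.5 deg segment retains at least
#'   three usable flank bins.
#' @param wedgeHalfWidth azimuthal half-width (deg) of the radial
#'   profile wedges about the preferred orientation.
#' @param minCounts minimum total unmasked counts for a pattern to be
#'   reduced.
#' @param porodMethod "log" (exponentiated log residual) or "linear".
#' @return A [ReductionConfig-class].
#' @export
reductionConfig <- function(dPeriodWindow = c(0.24, 0.32),
                            intermolWindow = c(1.9, 3.5),
                            usableQ = c(0.2, 5),
                            flankFraction = 0.2,
                            azFlankFractionD = 0.5,
                            azFlankFractionIM = 0.2,
                            wedgeHalfWidth = 20,
                            minCounts = 1000,
                            porodMethod = "log") {
    methods::new("ReductionConfig",
        dPeriodWindow = dPeriodWindow,
        intermolWindow = intermolWindow,
        usableQ = usableQ,
        flankFraction = flankFraction,
        azFlankFractionD = azFlankFractionD,
        azFlankFractionIM = azFlankFractionIM,
        nSegments = 720L,
        wedgeHalfWidth = wedgeHalfWidth,
        minCounts = minCounts,
        porodMethod = porodMethod)
}

#' Flank windows bracketing a peak window
#'
#' @param peakWindow numeric(2), nm^-1.
#' @param fraction flank width as a fraction of the window width.
#' @return list of two numeric(2): below and above the window.
#' @export
porodFlanks <- function(peakWindow, fraction = 0.2) {
    w <- diff(peakWindow) * fraction
    list(c(peakWindow[1] - w, peakWindow[1]),
         c(peakWindow[2], peakWindow[2] + w))
}

## Is azimuth az (deg, [0,360)) inside interval w = c(lo, hi)?
## lo > hi denotes an interval wrapping through 0.
azInWindow <- function(az, w) {
    w <- w %% 360
    if (w[1] <= w[2]) az >= w[1] & az <= w[2]
    else az >= w[1] | az <= w[2]
}

#' Friedel-paired wedge windows about an orientation
#'
#' @param center azimuth, deg.
#' @param halfWidth half-width, deg.
#' @return list of two c(lo, hi) azimuth intervals 180 deg apart.
#' @export
wedgeWindows <- function(center, halfWidth = 20) {
    list(c((center - halfWidth) %% 360, (center + halfWidth) %% 360),
         c((center + 180 - halfWidth) %% 360,
           (center + 180 + halfWidth) %% 360))
}

#' Azimuthally integrate a pattern into a radial profile
#'
#' Converts the image to polar coordinates and takes, per Q bin, the
#' mean of unmasked pixel intensities whose azimuth falls inside the
#' window(s). Empty bins carry NA intensity and zero pixel count.
#'
#' @param pattern numeric matrix (masked pixels NA or negative).
#' @param geometry a [DetectorGeometry-class].
#' @param qBreaks strictly increasing bin edges, nm^-1.
#' @param azimuthWindow a c(lo, hi) azimuth interval (deg) or a list of
#'   such; lo > hi wraps through 0. NULL integrates the full circle.
#' @param maps optional precomputed [geometryMaps()].
#' @return A [RadialProfile-class].
#' @export
azimuthalIntegrate <- function(pattern, geometry, qBreaks,
                               azimuthWindow = NULL, maps = NULL) {
    stopifnot(is.matrix(pattern), length(qBreaks) >= 3,
              all(diff(qBreaks) > 0))
    if (is.null(maps)) maps <- geometryMaps(geometry)
    if (!identical(dim(pattern), dim(maps$q)))
        stop("pattern shape does not match the detector geometry")
    if (!is.null(azimuthWindow) && !is.list(azimuthWindow))
        azimuthWindow <- list(azimuthWindow)
    sel <- !maps$beamstop & maps$q >= qBreaks[1] &
        maps$q <= qBreaks[length(qBreaks)]
    if (!is.null(azimuthWindow)) {
        inwin <- Reduce(`|`, lapply(azimuthWindow,
                                    function(w) azInWindow(maps$azimuth, w)))
        sel <- sel & inwin
    }
    v <- pattern[sel]
    qv <- maps$q[sel]
    ok <- is.finite(v) & v >= 0
    v <- v[ok]; qv <- qv[ok]
    if (!length(v))
        stop("azimuthal integration window contains no usable pixels ",
             "(window inside the beamstop or fully masked)")
    nb <- length(qBreaks) - 1
    bin <- findInterval(qv, qBreaks, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nb)
    sums <- rep(0, nb)
    rs <- rowsum(v, bin)
    sums[as.integer(rownames(rs))] <- rs[, 1]
    intensity <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
    centers <- (qBreaks[-1] + qBreaks[-(nb + 1)]) / 2
    methods::new("RadialProfile", q = centers, intensity = intensity,
                 npix = as.integer(cnt),
                 azimuthWindow = if (is.null(azimuthWindow)) list()
                                 else azimuthWindow)
}

#' Porod background subtraction over a peak window
#'
#' Fits a straight line to (ln Q, ln I) over two flank windows, then
#' subtracts it from ln I and exponentiates the residual (method
#' "log", the default), or subtracts exp(fit) in intensity units
#' (method "linear"). Bins with I <= 0 are flagged unusable (NA).
#'
#' @param profile a [RadialProfile-class] covering the peak and flank
#'   windows.
#' @param peakWindow numeric(2), nm^-1.
#' @param flankWindows list of two numeric(2); default
#'   [porodFlanks()] of the peak window.
#' @param method "log" or "linear".
#' @return A [PorodResult-class] restricted to the peak window, with
#'   net signal I/I_fit - 1 ("log") or I - I_fit ("linear").
#' @export
porodSubtract <- function(profile, peakWindow, flankWindows = NULL,
                          method = c("log", "linear")) {
    stopifnot(is(profile, "RadialProfile"), length(peakWindow) == 2)
    method <- match.arg(method)
    if (is.null(flankWindows)) flankWindows <- porodFlanks(peakWindow)
    stopifnot(length(flankWindows) == 2)
    q <- profile@q; I <- profile@intensity; n <- profile@npix
    usable <- n > 0 & is.finite(I)
    flankPts <- function(w, name) {
        inw <- q >= w[1] & q <= w[2] & usable
        if (any(inw) && !any(I[inw] > 0))
            stop(sprintf("non-positive intensities throughout the %s flank [%g, %g]",
                         name, w[1], w[2]))
        inw & I > 0
    }
    f1 <- flankPts(flankWindows[[1]], "lower")
    f2 <- flankPts(flankWindows[[2]], "upper")
    if (sum(f1) < 3)
        stop(sprintf("lower flank [%g, %g] has fewer than 3 usable bins",
                     flankWindows[[1]][1], flankWindows[[1]][2]))
    if (sum(f2) < 3)
        stop(sprintf("upper flank [%g, %g] has fewer than 3 usable bins",
                     flankWindows[[2]][1], flankWindows[[2]][2]))
    fl <- f1 | f2
    coef <- linfitCore(log(q[fl]), log(I[fl]))
    pk <- q >= peakWindow[1] & q <= peakWindow[2] & usable
    qp <- q[pk]
    bg <- exp(coef[1] + coef[2] * log(qp))
    Ip <- I[pk]
    net <- if (method == "log") {
        out <- rep(NA_real_, length(qp))
        pos <- Ip > 0
        out[pos] <- exp(log(Ip[pos]) - log(bg[pos])) - 1
        out
    } else {
        Ip - bg
    }
    methods::new("PorodResult", q = qp, net = net, intensity = Ip,
                 fit = coef, method = method, peakWindow = peakWindow,
                 flankWindows = flankWindows)
}

## Net signal of a PorodResult on the intensity scale (I - I_fit),
## used for all peak-position metrics.
netIntensityScale <- function(porod) {
    if (porod@method == "linear") return(porod@net)
    bg <- exp(porod@fit[1] + porod@fit[2] * log(porod@q))
    porod@net * bg
}

#' Fit the intermolecular peak with a Gaussian
#'
#' Nonlinear fit of A exp(-(Q - mu)^2 / 2 sigma^2) + c to the
#' background-subtracted intensity over the intermolecular window. The
#' center gives the intermolecular spacing 2 pi / mu.
#'
#' @param porod a [PorodResult-class] over the intermolecular window.
#' @return A [PeakFit-class] (method "gaussian"); `centerQ` is NA when
#'   the fit fails to converge or the center leaves the window.
#' @export
fitIntermolecularPeak <- function(porod) {
    stopifnot(is(porod, "PorodResult"))
    q <- porod@q
    y <- netIntensityScale(porod)
    ok <- is.finite(y)
    q <- q[ok]; y <- y[ok]
    miss <- methods::new("PeakFit", centerQ = NA_real_, width = NA_real_,
                         area = NA_real_, method = "gaussian")
    ## a peak must rise measurably above the background level, else
    ## the nonlinear fit would chase numerical residue
    floorSig <- 1e-8 * max(porod@intensity, na.rm = TRUE)
    if (length(q) < 5 || max(y) <= floorSig) return(miss)
    w0 <- pmax(y, 0)
    mu0 <- sum(q * w0) / sum(w0)
    s0 <- sqrt(pmax(sum(w0 * (q - mu0)^2) / sum(w0), 1e-6))
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-(q - mu)^2 / (2 * s^2)) + c0,
                          start = list(A = max(y), mu = mu0, s = s0,
                                       c0 = 0),
                          control = minpack.lm::nls.lm.control(
                              maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) return(miss)
    cf <- stats::coef(fit)
    if (!is.finite(cf["mu"]) || cf["mu"] < porod@peakWindow[1] ||
        cf["mu"] > porod@peakWindow[2] || cf["A"] <= 0)
        return(miss)
    methods::new("PeakFit", centerQ = unname(cf["mu"]),
                 width = abs(unname(cf["s"])),
                 area = unname(cf["A"]) * abs(unname(cf["s"])) *
                     sqrt(2 * pi),
                 method = "gaussian")
}

#' D-period from the third meridional order
#'
#' The peak center is the intensity-weighted mean of Q over the window
#' (centroid, not mode: the divergent-beam-broadened peak is blunt and
#' its mean is the robust location measure); the D-period is
#' 3 * 2 pi / center.
#'
#' @param porod a [PorodResult-class] over the D-period window.
#' @param order meridional order the window isolates (3).
#' @return list with elements `fit` ([PeakFit-class], method
#'   "centroid") and `dPeriod` (nm, NA when the window carries no
#'   positive signal).
#' @export
dPeriodFromProfile <- function(porod, order = 3) {
    stopifnot(is(porod, "PorodResult"))
    q <- porod@q
    y <- netIntensityScale(porod)
    ok <- is.finite(y)
    w <- pmax(y[ok], 0)
    miss <- list(fit = methods::new("PeakFit", centerQ = NA_real_,
                                    width = NA_real_, area = NA_real_,
                                    method = "centroid"),
                 dPeriod = NA_real_)
    floorSig <- 1e-8 * max(porod@intensity, na.rm = TRUE)
    if (sum(ok) < 5 || sum(w) <= floorSig) return(miss)
    ctr <- sum(q[ok] * w) / sum(w)
    list(fit = methods::new("PeakFit", centerQ = ctr, width = NA_real_,
                            area = sum(w), method = "centroid"),
         dPeriod = order * 2 * pi / ctr)
}

## ---- 720-segment azimuthal stage ----------------------------------

## Permutation-based grouped sums over a fixed cell partition: the
## sort order is computed once per geometry, after which per-pattern
## aggregation is a single cumulative-sum pass (rowsum() would re-hash
## the 10^6-scale group vector for every pattern).
groupedSumIndex <- function(cell, ncell) {
    perm <- order(cell)
    sorted <- cell[perm]
    ends <- c(which(diff(sorted) > 0L), length(sorted))
    list(perm = perm, ends = ends, ids = sorted[ends],
         counts = tabulate(cell, ncell), ncell = ncell)
}

## v must be NA-free and aligned with the cells of the index; callers
## fall back to rowsum() when masking applies.
groupedSums <- function(v, gsi) {
    cs <- cumsum(v[gsi$perm])
    out <- numeric(gsi$ncell)
    out[gsi$ids] <- cs[gsi$ends] -
        c(0, cs[gsi$ends[-length(gsi$ends)]])
    out
}

## Per-cell sums and counts for a pattern over an index carrying
## cell/gsi; handles masked or negative pixels via the slow path.
cellAggregate <- function(v, cell, gsi, ncell) {
    rng <- suppressWarnings(range(v))
    if (is.finite(rng[1]) && rng[1] >= 0)
        return(list(sums = groupedSums(v, gsi), counts = gsi$counts))
    ok <- is.finite(v) & v >= 0
    cnt <- tabulate(cell[ok], ncell)
    sums <- rep(0, ncell)
    if (any(ok)) {
        rs <- rowsum(v[ok], cell[ok])
        sums[as.integer(rownames(rs))] <- rs[, 1]
    }
    list(sums = sums, counts = cnt)
}

## Precompute, per geometry and Q-window scheme, the pixel selection
## and (segment, q-bin) cell index used by azimuthalPeakProfile. The
## q grid is nFlankBins + nPeakBins + nFlankBins contiguous zones.
##
## At low Q a 0.5 deg segment subtends less than a pixel, so pixel
## centers leave structural holes near the lattice axes; pixels are
## therefore split into subsample^2 equal-area subpixels assigned to
## cells individually (the usual polar-rebinning pixel splitting,
## approximated by area sampling). The subsampling factor defaults to
## the smallest value giving sub-half-segment azimuthal sampling at
## the inner annulus radius.
azimuthalSegmentIndex <- function(geometry, peakWindow, flankWindows,
                                  nPeakBins, nFlankBins, maps = NULL,
                                  nSegments = 720L, subsample = NULL) {
    if (is.null(maps)) maps <- geometryMaps(geometry)
    edges <- c(seq(flankWindows[[1]][1], flankWindows[[1]][2],
                   length.out = nFlankBins + 1L)[-(nFlankBins + 1L)],
               seq(peakWindow[1], peakWindow[2],
                   length.out = nPeakBins + 1L)[-(nPeakBins + 1L)],
               seq(flankWindows[[2]][1], flankWindows[[2]][2],
                   length.out = nFlankBins + 1L))
    if (any(diff(edges) <= 0))
        stop("flank windows must bracket the peak window without overlap")
    nb <- length(edges) - 1L
    pitch_mm <- geometry@pixelPitch / 1000
    ## inner annulus radius in px (small-angle approximation is ample)
    gpx <- 2 * pi * pitch_mm /
        (geometry@wavelength * geometry@sampleDetectorDistance)
    rmin <- max(edges[1] / gpx, geometry@beamstopRadius)
    if (is.null(subsample))
        subsample <- min(6L, max(1L, as.integer(
            ceiling(2.2 / (rmin * pi / 180 * (360 / nSegments))))))
    ## select parent pixels with a one-pixel halo so subpixels near the
    ## annulus boundary are not lost
    halo <- 1.5 * gpx
    sel <- which(!maps$beamstop & maps$q >= edges[1] - halo &
                 maps$q <= edges[nb + 1L] + halo)
    if (subsample > 1L) {
        rc <- arrayInd(sel, dim(maps$q))
        off <- (seq_len(subsample) - (subsample + 1) / 2) / subsample
        grid <- expand.grid(oy = off, ox = off)
        nsub <- nrow(grid)
        npar <- length(sel)
        dx <- (rep(rc[, 2], nsub) + rep(grid$ox, each = npar) -
               geometry@beamCenter[1]) * pitch_mm
        dy <- (rep(rc[, 1], nsub) + rep(grid$oy, each = npar) -
               geometry@beamCenter[2]) * pitch_mm
        r <- sqrt(dx^2 + dy^2)
        qv <- (4 * pi / geometry@wavelength) *
            sin(atan(r / geometry@sampleDetectorDistance) / 2)
        azv <- (atan2(dy, dx) * 180 / pi) %% 360
        parent <- rep(sel, nsub)
        w <- 1 / nsub
    } else {
        parent <- sel
        qv <- maps$q[sel]
        azv <- maps$azimuth[sel]
        w <- 1
    }
    bin <- findInterval(qv, edges)
    keep <- bin >= 1L & bin <= nb
    parent <- parent[keep]; bin <- bin[keep]
    seg <- pmin(floor(azv[keep] / (360 / nSegments)) + 1L, nSegments)
    zone <- rep(2L, nb)
    zone[seq_len(nFlankBins)] <- 1L
    zone[(nb - nFlankBins + 1L):nb] <- 3L
    cell <- seg + nSegments * (bin - 1L)
    list(idx = parent, cell = cell,
         gsi = groupedSumIndex(cell, nSegments * nb),
         weight = w, subsample = subsample,
         nSegments = nSegments, nBins = nb, zone = zone,
         qCenters = (edges[-1] + edges[-(nb + 1L)]) / 2,
         peakWindow = peakWindow, flankWindows = flankWindows)
}

#' Azimuthal profile of background-subtracted peak signal
#'
#' Splits the pattern into 720 azimuthal segments of 0.5 deg and
#' repeats the Porod background subtraction independently in each
#' segment over the given peak window; the segment signal is the total
#' net peak signal. Segments whose flanks do not support the fit
#' (fewer than 3 usable bins on either side) are flagged missing; the
#' profile is rejected when more than half the segments are missing.
#'
#' @param pattern numeric matrix.
#' @param geometry a [DetectorGeometry-class].
#' @param peakWindow numeric(2), nm^-1.
#' @param flankWindows list of two numeric(2); default
#'   [porodFlanks()] of the peak window.
#' @param nPeakBins,nFlankBins q bins per zone of the per-segment
#'   radial profile.
#' @param method "log" or "linear" net signal.
#' @param maps optional [geometryMaps()].
#' @param segIndex optional precomputed segment index (used by the
#'   scan reducer to share work across patterns).
#' @param subsample pixel-splitting factor (see
#'   `azimuthalSegmentIndex`); NULL chooses automatically from the
#'   inner annulus radius.
#' @return An [AzimuthalProfile-class].
#' @export
azimuthalPeakProfile <- function(pattern, geometry, peakWindow,
                                 flankWindows = NULL,
                                 nPeakBins = 8L, nFlankBins = 4L,
                                 method = c("log", "linear"),
                                 maps = NULL, segIndex = NULL,
                                 subsample = NULL) {
    method <- match.arg(method)
    if (is.null(flankWindows)) flankWindows <- porodFlanks(peakWindow)
    if (is.null(segIndex))
        segIndex <- azimuthalSegmentIndex(geometry, peakWindow,
                                          flankWindows, nPeakBins,
                                          nFlankBins, maps = maps,
                                          subsample = subsample)
    ns <- segIndex$nSegments
    nb <- segIndex$nBins
    v <- pattern[segIndex$idx]
    ncell <- ns * nb
    agg <- cellAggregate(v, segIndex$cell, segIndex$gsi, ncell)
    cnt <- agg$counts
    area <- matrix(cnt * segIndex$weight, nrow = ns, ncol = nb)
    meanI <- matrix(ifelse(cnt > 0, agg$sums / pmax(cnt, 1), NA_real_),
                    nrow = ns, ncol = nb)
    lnI <- suppressWarnings(log(meanI))     # NaN where I <= 0: unusable
    lnI[!is.finite(lnI)] <- NA_real_
    x <- log(segIndex$qCenters)
    fb <- which(segIndex$zone != 2L)
    f1b <- which(segIndex$zone == 1L)
    f2b <- which(segIndex$zone == 3L)
    pkb <- which(segIndex$zone == 2L)
    Y <- lnI[, fb, drop = FALSE]
    U <- is.finite(Y) + 0
    Y0 <- Y; Y0[U == 0] <- 0
    xf <- x[fb]
    n1 <- rowSums(U[, match(f1b, fb), drop = FALSE])
    n2 <- rowSums(U[, match(f2b, fb), drop = FALSE])
    n <- n1 + n2
    Sx <- as.vector(U %*% xf)
    Sy <- rowSums(Y0)
    Sxx <- as.vector(U %*% xf^2)
    Sxy <- as.vector(Y0 %*% xf)
    den <- n * Sxx - Sx^2
    good <- n1 >= 3 & n2 >= 3 & den > 0
    slope <- ifelse(good, (n * Sxy - Sx * Sy) / ifelse(den > 0, den, 1),
                    NA_real_)
    icpt <- ifelse(good, (Sy - slope * Sx) / pmax(n, 1), NA_real_)
    xp <- x[pkb]
    fitln <- outer(icpt, xp, function(a, xx) a) +
        outer(slope, xp, function(b, xx) b * xx)
    netpk <- if (method == "log") {
        exp(lnI[, pkb, drop = FALSE] - fitln) - 1
    } else {
        meanI[, pkb, drop = FALSE] - exp(fitln)
    }
    nUse <- rowSums(is.finite(netpk))
    ## total (pixel-area-weighted) net peak signal per segment
    signal <- rowSums(netpk * area[, pkb, drop = FALSE], na.rm = TRUE)
    missing <- !good | nUse == 0
    signal[missing] <- NA_real_
    if (mean(missing) > 0.5)
        stop(sprintf("azimuthal profile rejected: %d of %d segments unusable",
                     sum(missing), ns))
    methods::new("AzimuthalProfile",
                 azimuth = (seq_len(ns) - 0.5) * (360 / ns),
                 signal = signal, missing = missing)
}

#' FWHM and preferred orientation of an azimuthal profile
#'
#' Folds the 720-segment profile to its 180 deg fibre-symmetric period,
#' locates the dominant lobe and finds the half-maximum crossings by
#' linear interpolation between 0.5 deg bins (missing bins are filled
#' by linear interpolation first). A lobe wider than the half-period
#' yields FWHM 180 with a flag.
#'
#' @param profile an [AzimuthalProfile-class].
#' @return list with `fwhm` (deg), `orientation` (deg in [0, 180)),
#'   and logical `flagged`.
#' @export
profileFWHM <- function(profile) {
    stopifnot(is(profile, "AzimuthalProfile"))
    s <- profile@signal
    half1 <- s[1:360]; half2 <- s[361:720]
    folded <- rowMeans(cbind(half1, half2), na.rm = TRUE)
    folded[!is.finite(folded)] <- NA_real_
    if (all(is.na(folded)))
        stop("azimuthal profile has no usable folded bins")
    n <- 360L
    pk <- which.max(replace(folded, is.na(folded), -Inf))
    maxv <- folded[pk]
    orientation <- (pk - 0.5) * 0.5
    if (!is.finite(maxv) || maxv <= 0)
        return(list(fwhm = 180, orientation = orientation, flagged = TRUE))
    ## rotate so the peak sits at index 181, fill gaps by interpolation
    ord <- ((pk - 1 + (seq_len(n) - 181)) %% n) + 1
    y <- folded[ord]
    if (anyNA(y)) {
        ii <- which(is.finite(y))
        y <- stats::approx(ii, y[ii], xout = seq_len(n), rule = 2)$y
    }
    fwhm0 <- crossingWidth(y, maxv / 2, n)
    if (is.finite(fwhm0) && fwhm0 > 5) {
        ## light circular smoothing (3-bin boxcar, 1.5 deg) damps the
        ## polar-rebinning sampling noise; it widens a Gaussian lobe by
        ## < 0.01 deg at these dispersions, and is skipped for
        ## near-delta lobes where it would dominate the width
        y <- (y + y[c(2:n, 1)] + y[c(n, 1:(n - 1))]) / 3
        maxv <- max(y)
        fwhm0 <- crossingWidth(y, maxv / 2, n)
    }
    ## refine the lobe apex with a local quadratic over ~ +/-0.7 sigma
    ## (estimated from the first-pass FWHM): the raw bin maximum rides
    ## on the sampling noise and would bias the half-maximum level
    ## high (and the FWHM low)
    if (is.finite(fwhm0)) {
        hw <- max(3L, min(40L, round(0.7 * fwhm0 / FWHM_FACTOR / 0.5)))
        win <- (181 - hw):(181 + hw)
        qf <- stats::lm(y[win] ~ stats::poly(win, 2, raw = TRUE))
        cf <- stats::coef(qf)
        if (is.finite(cf[3]) && cf[3] < 0) {
            vtx <- unname(-cf[2] / (2 * cf[3]))
            if (vtx > 181 - hw && vtx < 181 + hw) {
                maxv <- unname(cf[1] + cf[2] * vtx + cf[3] * vtx^2)
                orientation <- (orientation + (vtx - 181) * 0.5) %% 180
            }
        }
    }
    fw <- crossingWidth(y, maxv / 2, n)
    if (!is.finite(fw))
        return(list(fwhm = 180, orientation = orientation, flagged = TRUE))
    list(fwhm = fw, orientation = orientation, flagged = FALSE)
}

## Half-level crossing separation (deg) around the apex at index 181
## of a rotated 360-bin half-period profile; ties at the level break
## toward the wider width (strict drop below the level required).
crossingWidth <- function(y, level, n) {
    right <- NA_real_
    for (j in 181:(n - 1)) {
        if (y[j] >= level && y[j + 1] < level) {
            right <- j + (y[j] - level) / (y[j] - y[j + 1])
            break
        }
    }
    left <- NA_real_
    for (j in 181:2) {
        if (y[j] >= level && y[j - 1] < level) {
            left <- j - (y[j] - level) / (y[j] - y[j - 1])
            break
        }
    }
    if (is.na(left) || is.na(right)) return(NA_real_)
    (right - left) * 0.5
}

#' Relative supramolecular twist from the two dispersions
#'
#' The molecular azimuthal dispersion convolves the fibril orientation
#' distribution with the intrafibrillar molecular spread; under the
#' Gaussian-quadrature surrogate the raw twist is
#' sqrt(max(sigma_mol^2 - sigma_fib^2, 0)) with sigma = FWHM / 2.3548.
#' Normalizing by the mean raw twist of the non-mineralizing reference
#' gives the relative twist.
#'
#' @param fibrilFWHM,molecularFWHM dispersion FWHMs, deg (vectorized).
#' @param nmReference mean raw twist of the NM reference set (deg);
#'   NULL returns only raw twists.
#' @return list with `raw` (deg), `relative` (dimensionless or NA),
#'   and logical `clamped` (TRUE where molecular < fibril dispersion).
#' @export
estimateRelativeTwist <- function(fibrilFWHM, molecularFWHM,
                                  nmReference = NULL) {
    sf <- fibrilFWHM / FWHM_FACTOR
    sm <- molecularFWHM / FWHM_FACTOR
    d2 <- sm^2 - sf^2
    clamped <- is.finite(d2) & d2 < 0
    raw <- sqrt(pmax(d2, 0))
    rel <- if (is.null(nmReference)) rep(NA_real_, length(raw))
           else {
               if (!is.finite(nmReference) || nmReference <= 0)
                   stop("nmReference must be a positive twist (deg)")
               raw / nmReference
           }
    list(raw = raw, relative = rel, clamped = clamped)
}

## ---- full per-pattern reduction -----------------------------------

#' Precompute geometry-dependent indices for the reduction
#'
#' Shares the pixel Q/azimuth maps, the two azimuthal-segment index
#' structures and the radial-profile pixel sets across all patterns of
#' a scan.
#'
#' @param geometry a [DetectorGeometry-class].
#' @param config a [ReductionConfig-class].
#' @param maps optional precomputed [geometryMaps()].
#' @return An opaque list passed to [reducePattern()].
#' @export
reductionCache <- function(geometry, config = reductionConfig(),
                           maps = NULL) {
    stopifnot(is(geometry, "DetectorGeometry"),
              is(config, "ReductionConfig"))
    methods::validObject(config)
    if (is.null(maps)) maps <- geometryMaps(geometry)
    lim <- geometryQLimits(geometry)
    fl_im_r <- porodFlanks(config@intermolWindow, config@flankFraction)
    if (lim[["qmax"]] < fl_im_r[[2]][2])
        stop(sprintf(paste0("geometry covers Q <= %.2f nm^-1 at all ",
                            "azimuths; the intermolecular window plus ",
                            "flanks needs %.2f nm^-1"),
                     lim[["qmax"]], fl_im_r[[2]][2]))
    ## radial profiles are aggregated on a (720 segments x fine-Q)
    ## grid once per pattern; a wedge profile is then a row selection
    ## (wedge membership resolved at 0.5 deg segment granularity)
    radialEntry <- function(peakWindow, flankWindows, binWidth) {
        lo <- flankWindows[[1]][1]; hi <- flankWindows[[2]][2]
        breaks <- seq(lo, hi, by = binWidth)
        if (breaks[length(breaks)] < hi)
            breaks <- c(breaks, hi)
        nb <- length(breaks) - 1L
        sel <- which(!maps$beamstop & maps$q >= lo & maps$q <= hi)
        bin <- findInterval(maps$q[sel], breaks,
                            rightmost.closed = TRUE)
        seg <- pmin(floor(maps$azimuth[sel] / 0.5) + 1L, 720L)
        cell <- seg + 720L * (bin - 1L)
        list(idx = sel, cell = cell, nBins = nb,
             gsi = groupedSumIndex(cell, 720L * nb),
             breaks = breaks,
             centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
             segCenters = (seq_len(720L) - 0.5) * 0.5,
             peakWindow = peakWindow, flankWindows = flankWindows)
    }
    fl_d_r <- porodFlanks(config@dPeriodWindow, config@flankFraction)
    fl_d_az <- porodFlanks(config@dPeriodWindow, config@azFlankFractionD)
    fl_im_az <- porodFlanks(config@intermolWindow,
                            config@azFlankFractionIM)
    list(maps = maps, config = config,
         segD = azimuthalSegmentIndex(geometry, config@dPeriodWindow,
                                      fl_d_az, AZ_PEAK_BINS_D,
                                      AZ_FLANK_BINS_D, maps = maps),
         segIM = azimuthalSegmentIndex(geometry, config@intermolWindow,
                                       fl_im_az, AZ_PEAK_BINS_IM,
                                       AZ_FLANK_BINS_IM, maps = maps),
         radD = radialEntry(config@dPeriodWindow, fl_d_r, RADIAL_BIN_D),
         radIM = radialEntry(config@intermolWindow, fl_im_r,
                             RADIAL_BIN_IM))
}

## Wedge-restricted radial profile from a cache entry (fast path;
## wedge membership at 0.5 deg segment granularity).
radialProfileCached <- function(pattern, entry, windows) {
    v <- pattern[entry$idx]
    nb <- entry$nBins
    agg <- cellAggregate(v, entry$cell, entry$gsi, 720L * nb)
    segIn <- Reduce(`|`, lapply(windows, function(w)
        azInWindow(entry$segCenters, w)))
    if (!any(segIn))
        stop("azimuth window selects no segments")
    cnt <- colSums(matrix(agg$counts, 720L, nb)[segIn, , drop = FALSE])
    sums <- colSums(matrix(agg$sums, 720L, nb)[segIn, , drop = FALSE])
    methods::new("RadialProfile", q = entry$centers,
                 intensity = ifelse(cnt > 0, sums / pmax(cnt, 1),
                                    NA_real_),
                 npix = as.integer(cnt), azimuthWindow = windows)
}

#' Reduce one scatter pattern to its five structural metrics
#'
#' Runs the full chain: D-period azimuthal profile (fibril dispersion
#' FWHM and preferred fibril orientation), intermolecular azimuthal
#' profile (molecular dispersion), meridional radial profile in a
#' +/-20 deg wedge about the preferred orientation (D-period
#' centroid), equatorial radial profile 90 deg away (Gaussian
#' intermolecular spacing) and the quadrature twist estimate. Failing
#' sub-metrics propagate as NA fields with flags, never as errors.
#'
#' @param pattern numeric matrix.
#' @param geometry a [DetectorGeometry-class].
#' @param config a [ReductionConfig-class].
#' @param cache optional [reductionCache()] (built on the fly if
#'   absent).
#' @return An [XRDMetrics-class]; `relativeTwist` is NA until
#'   normalized at scan level (see [reduceScan()]).
#' @export
reducePattern <- function(pattern, geometry,
                          config = reductionConfig(), cache = NULL) {
    if (is.null(cache)) cache <- reductionCache(geometry, config)
    flags <- character()
    na_metrics <- function(flags)
        methods::new("XRDMetrics", dPeriod = NA_real_,
                     intermolSpacing = NA_real_, fibrilFWHM = NA_real_,
                     molecularFWHM = NA_real_, rawTwist = NA_real_,
                     relativeTwist = NA_real_,
                     preferredOrientation = NA_real_, flags = flags)
    total <- sum(pattern[!cache$maps$beamstop], na.rm = TRUE)
    if (!is.finite(total) || total < config@minCounts)
        return(na_metrics("low_signal"))
    ## fibril dispersion + preferred orientation (D-period arc)
    fib <- tryCatch({
        prof <- azimuthalPeakProfile(pattern, geometry,
                                     config@dPeriodWindow,
                                     segIndex = cache$segD,
                                     method = config@porodMethod)
        profileFWHM(prof)
    }, error = function(e) NULL)
    if (is.null(fib)) return(na_metrics("fibril_profile_failed"))
    if (fib$flagged) flags <- c(flags, "fibril_fwhm_degenerate")
    po <- fib$orientation
    ## molecular dispersion (equatorial intermolecular arc)
    mol <- tryCatch({
        prof <- azimuthalPeakProfile(pattern, geometry,
                                     config@intermolWindow,
                                     segIndex = cache$segIM,
                                     method = config@porodMethod)
        profileFWHM(prof)
    }, error = function(e) NULL)
    if (is.null(mol)) {
        flags <- c(flags, "molecular_profile_failed")
        molFWHM <- NA_real_
    } else {
        if (mol$flagged) flags <- c(flags, "molecular_fwhm_degenerate")
        molFWHM <- mol$fwhm
    }
    ## meridional radial profile -> D-period centroid
    dper <- tryCatch({
        prof <- radialProfileCached(pattern, cache$radD,
                                    wedgeWindows(po,
                                                 config@wedgeHalfWidth))
        ps <- porodSubtract(prof, config@dPeriodWindow,
                            cache$radD$flankWindows,
                            method = config@porodMethod)
        dPeriodFromProfile(ps)$dPeriod
    }, error = function(e) NA_real_)
    if (is.na(dper)) flags <- c(flags, "d_period_missing")
    ## equatorial radial profile -> intermolecular spacing
    spacing <- tryCatch({
        prof <- radialProfileCached(pattern, cache$radIM,
                                    wedgeWindows(po + 90,
                                                 config@wedgeHalfWidth))
        ps <- porodSubtract(prof, config@intermolWindow,
                            cache$radIM$flankWindows,
                            method = config@porodMethod)
        pf <- fitIntermolecularPeak(ps)
        if (is.na(pf@centerQ)) NA_real_ else qToSpacing(pf@centerQ)
    }, error = function(e) NA_real_)
    if (is.na(spacing)) flags <- c(flags, "intermolecular_missing")
    tw <- estimateRelativeTwist(fib$fwhm, molFWHM)
    if (isTRUE(tw$clamped)) flags <- c(flags, "twist_clamped")
    methods::new("XRDMetrics", dPeriod = dper,
                 intermolSpacing = spacing, fibrilFWHM = fib$fwhm,
                 molecularFWHM = molFWHM, rawTwist = tw$raw,
                 relativeTwist = NA_real_, preferredOrientation = po,
                 flags = flags)
}

metricsRow <- function(m) {
    data.frame(d_period_nm = m@dPeriod,
               intermol_spacing_nm = m@intermolSpacing,
               fibril_fwhm_deg = m@fibrilFWHM,
               molecular_fwhm_deg = m@molecularFWHM,
               raw_twist_deg = m@rawTwist,
               relative_twist = m@relativeTwist,
               preferred_orientation_deg = m@preferredOrientation,
               flags = paste(m@flags, collapse = ";"))
}

#' Normalize raw twist by the NM-region mean
#'
#' @param metrics a DataFrame/data.frame with columns `raw_twist_deg`
#'   and `region`.
#' @param reference region label of the reference set ("NM").
#' @return The input with `relative_twist` filled in (NA when the
#'   reference region has no valid twists).
#' @export
normalizeTwist <- function(metrics, reference = "NM") {
    ref <- metrics$raw_twist_deg[metrics$region == reference]
    ref <- ref[is.finite(ref)]
    if (length(ref) && mean(ref) > 0)
        metrics$relative_twist <- metrics$raw_twist_deg / mean(ref)
    metrics
}

#' Reduce a scatter map (or layout) to a metrics table
#'
#' Applies [reducePattern()] to every pattern and normalizes the twist
#' against the NM region. `reduceLayout()` generates each pattern on
#' the fly from a [RegionLayout-class] and discards it after
#' reduction, so full scans never need to be held in memory.
#'
#' @param map a [ScatterMap-class].
#' @param config a [ReductionConfig-class].
#' @param cache optional [reductionCache()].
#' @param verbose log per-pattern progress to stderr.
#' @return An [S4Vectors::DataFrame] with one row per pattern:
#'   position columns, the five metrics, preferred orientation and
#'   flags.
#' @export
reduceScan <- function(map, config = reductionConfig(), cache = NULL,
                       verbose = FALSE) {
    stopifnot(is(map, "ScatterMap"))
    if (is.null(cache)) cache <- reductionCache(map@geometry, config)
    rows <- lapply(seq_along(map@patterns), function(i) {
        if (verbose && i %% 25 == 1)
            message("reducing pattern ", i, "/", length(map@patterns))
        metricsRow(reducePattern(map@patterns[[i]], map@geometry,
                                 config, cache))
    })
    out <- cbind(map@positions, do.call(rbind, rows))
    S4Vectors::DataFrame(normalizeTwist(out))
}

#' @rdname reduceScan
#' @param layout a [RegionLayout-class].
#' @param geometry a [DetectorGeometry-class].
#' @export
reduceLayout <- function(layout, geometry, config = reductionConfig(),
                         cache = NULL, verbose = FALSE) {
    stopifnot(is(layout, "RegionLayout"))
    methods::validObject(layout)
    if (is.null(cache)) cache <- reductionCache(geometry, config)
    pos <- serpentinePositions(nrow(layout@labels), ncol(layout@labels),
                               layout@pitch)
    pos$region <- layout@labels[cbind(pos$row, pos$col)]
    rows <- lapply(seq_len(nrow(pos)), function(i) {
        if (verbose && i %% 25 == 1)
            message("position ", i, "/", nrow(pos))
        scene <- layout@scenes[[pos$region[i]]]
        pat <- generateScatterPattern(scene, geometry,
                                      maps = cache$maps,
                                      seed = scene@seed + pos$index[i])
        metricsRow(reducePattern(pat, geometry, config, cache))
    })
    out <- cbind(pos, do.call(rbind, rows))
    S4Vectors::DataFrame(normalizeTwist(out))
}

## ---- horizontal binning -------------------------------------------

#' Horizontal scan binning: positions only
#'
#' Bookkeeping form of the horizontal binning: groups each scan row
#' into consecutive runs of `factor` positions along x, dropping any
#' trailing remainder, and returns the group centers.
#'
#' @param positions data.frame with columns row, col, x_um, y_um.
#' @param factor integer >= 1.
#' @return data.frame with one row per group: row, col (center),
#'   x_um, y_um, n_members.
#' @examples
#' p <- serpentinePositions(209, 2500, pitch = c(20, 100))
#' nrow(binScanPositions(p, 5))   # 104500 patterns at 100 um pitch
#' @export
binScanPositions <- function(positions, factor) {
    factor <- as.integer(factor)
    if (is.na(factor) || factor < 1)
        stop("binning factor must be a positive integer")
    ord <- order(positions$row, positions$col)
    p <- positions[ord, ]
    grp <- stats::ave(p$col, p$row,
                      FUN = function(cc) (seq_along(cc) - 1) %/% factor)
    nper <- stats::ave(p$col, p$row, grp, FUN = length)
    keep <- nper == factor
    p <- p[keep, ]; grp <- grp[keep]
    key <- interaction(p$row, grp, drop = TRUE)
    agg <- function(v) as.vector(tapply(v, key, mean))
    out <- data.frame(row = as.vector(tapply(p$row, key, unique)),
                      col = agg(p$col), x_um = agg(p$x_um),
                      y_um = agg(p$y_um),
                      n_members = as.vector(tapply(p$col, key, length)))
    out[order(out$row, out$col), , drop = FALSE]
}

#' Horizontal scan binning of a scatter map
#'
#' Sums consecutive groups of `factor` patterns along x within each
#' scan row (improving signal-to-noise), replaces positions by the
#' group centers and drops any trailing remainder. `factor = 1` is the
#' identity.
#'
#' @param map a [ScatterMap-class].
#' @param factor integer >= 1.
#' @return A [ScatterMap-class] with floor(rowCount / factor) patterns
#'   per row.
#' @export
binScanHorizontal <- function(map, factor) {
    stopifnot(is(map, "ScatterMap"))
    factor <- as.integer(factor)
    if (is.na(factor) || factor < 1)
        stop("binning factor must be a positive integer")
    if (factor == 1) return(map)
    pos <- map@positions
    ord <- order(pos$row, pos$col)
    pos <- pos[ord, ]
    pats <- map@patterns[ord]
    grp <- stats::ave(pos$col, pos$row,
                      FUN = function(cc) (seq_along(cc) - 1) %/% factor)
    key <- paste(pos$row, grp, sep = "_")
    nper <- stats::ave(pos$col, pos$row, grp, FUN = length)
    keep <- nper == factor
    pos <- pos[keep, ]; pats <- pats[keep]; key <- key[keep]
    ukeys <- unique(key)
    newPats <- vector("list", length(ukeys))
    newPos <- vector("list", length(ukeys))
    for (i in seq_along(ukeys)) {
        sel <- which(key == ukeys[i])
        acc <- pats[[sel[1]]]
        for (j in sel[-1]) acc <- acc + pats[[j]]
        newPats[[i]] <- acc
        regions <- unique(pos$region[sel])
        newPos[[i]] <- data.frame(
            index = i, row = pos$row[sel[1]],
            col = mean(pos$col[sel]), x_um = mean(pos$x_um[sel]),
            y_um = mean(pos$y_um[sel]),
            region = if (length(regions) == 1) regions else NA_character_)
    }
    posdf <- do.call(rbind, newPos)
    ord2 <- order(posdf$row, posdf$col)
    posdf <- posdf[ord2, ]
    posdf$index <- seq_len(nrow(posdf))
    methods::new("ScatterMap", patterns = newPats[ord2],
                 positions = posdf, geometry = map@geometry)
}
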