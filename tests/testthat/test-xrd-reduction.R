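test_that("azimuthal integration is exact on isotropic input", {
    g <- smallGeometry(); maps <- smallMaps()
    flat <- matrix(5, 256, 256)
    brk <- seq(0.3, 3.8, length.out = 101)
    prof <- azimuthalIntegrate(flat, g, brk, maps = maps)
    expect_true(all(qValues(prof) > 0.3 & qValues(prof) < 3.8))
    expect_true(all(abs(prof@intensity[prof@npix > 0] - 5) < 1e-12))
    ## full circle equals the npix-weighted combination of two halves
    ph1 <- azimuthalIntegrate(flat, g, brk, c(0, 180), maps = maps)
    ph2 <- azimuthalIntegrate(flat, g, brk, c(180, 360), maps = maps)
    n1 <- ph1@npix; n2 <- ph2@npix
    i1 <- ifelse(n1 > 0, ph1@intensity, 0)
    i2 <- ifelse(n2 > 0, ph2@intensity, 0)
    comb <- ifelse(n1 + n2 > 0, (i1 * n1 + i2 * n2) / (n1 + n2), NA)
    both <- prof@npix > 0
    ## boundary pixels at azimuth exactly 0/180 may fall in both halves
    expect_equal(comb[both], prof@intensity[both], tolerance = 1e-6)
})

test_that("a Porod image integrates to a q^-4 profile within 1%", {
    g <- synthGeometry(); maps <- synthCache()$maps
    pat <- 12 * maps$q^-4
    pat[maps$beamstop] <- NA
    brk <- seq(0.24, 3.8, length.out = 301)
    prof <- azimuthalIntegrate(pat, g, brk, maps = maps)
    ok <- prof@npix > 0
    rel <- abs(prof@intensity[ok] / (12 * qValues(prof)[ok]^-4) - 1)
    expect_lt(max(rel), 0.01)
})

test_that("integration windows inside the beamstop are rejected", {
    g <- smallGeometry(); maps <- smallMaps()
    flat <- matrix(1, 256, 256)
    expect_error(
        azimuthalIntegrate(flat, g, seq(0.001, 0.1, length.out = 10),
                           maps = maps),
        "no usable pixels")
})

test_that("Porod subtraction recovers slope -4 and a null residual", {
    prof <- analyticProfile(1.58, 3.82, n = 220, amp = 10)
    ps <- porodSubtract(prof, c(1.9, 3.5))
    expect_equal(ps@fit[2], -4, tolerance = 1e-3)
    expect_lt(max(abs(netSignal(ps))), 1e-6)
    ## linear method likewise
    psl <- porodSubtract(prof, c(1.9, 3.5), method = "linear")
    expect_lt(max(abs(netSignal(psl) / prof@intensity[1])), 1e-6)
})

test_that("Porod subtraction flags unusable flanks", {
    prof <- analyticProfile(1.58, 3.82, n = 220)
    bad <- prof
    bad@intensity[qValues(bad) < 1.9] <- 0
    expect_error(porodSubtract(bad, c(1.9, 3.5)), "lower flank")
    sparse <- analyticProfile(1.88, 3.52, n = 100)
    expect_error(porodSubtract(sparse, c(1.9, 3.5)),
                 "fewer than 3 usable bins")
})

test_that("a known Gaussian peak on Porod background is recovered", {
    peak <- function(q) 3 * exp(-(q - 2.7)^2 / (2 * 0.15^2))
    prof <- analyticProfile(1.58, 3.82, n = 220, amp = 10, peak = peak)
    ps <- porodSubtract(prof, c(1.9, 3.5))
    fit <- fitIntermolecularPeak(ps)
    binw <- diff(qValues(prof)[1:2])
    expect_lt(abs(fit@centerQ - 2.7), binw)
    expect_equal(qToSpacing(fit@centerQ), 2.32710566932577,
                 tolerance = 1e-3)
    ## symmetric peak: Gaussian center within half a bin of the argmax
    ## of the intensity-scale net signal
    psl <- porodSubtract(prof, c(1.9, 3.5), method = "linear")
    am <- qValues(psl)[which.max(netSignal(psl))]
    fitl <- fitIntermolecularPeak(psl)
    expect_lt(abs(fitl@centerQ - am), binw / 2 + 1e-9)
})

test_that("non-converging or out-of-window peak fits come back missing", {
    prof <- analyticProfile(1.58, 3.82, n = 220, amp = 10)
    ps <- porodSubtract(prof, c(1.9, 3.5))
    fit <- fitIntermolecularPeak(ps)     # background only: no peak
    expect_true(is.na(fit@centerQ))
})

test_that("D-period centroid follows its quadrature oracle", {
    ## uniform net signal over the window: centroid 0.28 exactly
    prof <- analyticProfile(0.224, 0.336, n = 280, amp = 10,
                            peak = function(q)
                                ifelse(q > 0.24 & q < 0.32, 50, 0))
    ps <- porodSubtract(prof, c(0.24, 0.32))
    res <- dPeriodFromProfile(ps)
    expect_equal(res$fit@centerQ, 0.28, tolerance = 1e-9)
    expect_equal(res$dPeriod, 3 * 2 * pi / 0.28, tolerance = 1e-6)
    ## skewed triangular peak against an independent quadrature oracle
    ## (weights taken from the known generator function, not the fit)
    tri <- function(q)
        30 * pmax(0, pmin((q - 0.25) / 0.01, (0.31 - q) / 0.05))
    ptri <- analyticProfile(0.224, 0.336, n = 560, amp = 10, peak = tri)
    pstri <- porodSubtract(ptri, c(0.24, 0.32))
    qt <- qValues(pstri)
    wt <- tri(qt)
    expect_equal(dPeriodFromProfile(pstri)$fit@centerQ,
                 sum(qt * wt) / sum(wt), tolerance = 1e-6)
    ## symmetric Gaussian at the third-order position -> d ~ 67.0 nm
    gpk <- function(q) 30 * exp(-(q - 0.2813)^2 / (2 * 0.01^2))
    pg <- analyticProfile(0.224, 0.336, n = 560, amp = 10, peak = gpk)
    d <- dPeriodFromProfile(porodSubtract(pg, c(0.24, 0.32)))$dPeriod
    expect_equal(d, 67.0087306133621, tolerance = 0.1 / 67)
})

test_that("empty or negative windows yield missing D-period", {
    prof <- analyticProfile(0.224, 0.336, n = 280, amp = 10)
    ps <- porodSubtract(prof, c(0.24, 0.32))
    res <- dPeriodFromProfile(ps)
    expect_true(is.na(res$dPeriod))   # no signal above background
})

test_that("azimuthal FWHM matches 2.3548 sigma on wrapped Gaussians", {
    az <- (seq_len(720) - 0.5) * 0.5
    mk <- function(sigma, center = 90)
        new("AzimuthalProfile", azimuth = az,
            signal = collagenHier:::wrappedGaussian(az %% 180, center,
                                                    sigma),
            missing = rep(FALSE, 720))
    for (s in c(4, 10, 16)) {
        res <- profileFWHM(mk(s))
        expect_equal(res$fwhm, 2 * sqrt(2 * log(2)) * s,
                     tolerance = 0.5 / (2.3548 * s))
        expect_equal(res$orientation, 90, tolerance = 0.5)
        expect_false(res$flagged)
    }
})

test_that("degenerate azimuthal profiles are flagged", {
    az <- (seq_len(720) - 0.5) * 0.5
    delta <- rep(0, 720); delta[181] <- 1; delta[541] <- 1
    res <- profileFWHM(new("AzimuthalProfile", azimuth = az,
                           signal = delta, missing = rep(FALSE, 720)))
    expect_lte(res$fwhm, 1)
    flat <- profileFWHM(new("AzimuthalProfile", azimuth = az,
                            signal = rep(1, 720),
                            missing = rep(FALSE, 720)))
    expect_true(flat$flagged)
    expect_equal(flat$fwhm, 180)
})

test_that("twist deconvolution follows the quadrature model", {
    fw <- 2 * sqrt(2 * log(2))
    ## no intrafibrillar spread
    expect_equal(estimateRelativeTwist(20, 20)$raw, 0)
    ## exact quadrature round trip: sigma_fib 6.5, twist 8
    res <- estimateRelativeTwist(fw * 6.5, fw * sqrt(6.5^2 + 8^2))
    expect_equal(res$raw, 8, tolerance = 1e-12)
    ## clamped when molecular < fibril dispersion
    cl <- estimateRelativeTwist(30, 25)
    expect_equal(cl$raw, 0)
    expect_true(cl$clamped)
    ## normalization: mean relative twist over the reference set is 1
    raws <- estimateRelativeTwist(rep(fw * 5, 4),
                                  fw * sqrt(25 + c(36, 49, 64, 81)))$raw
    rel <- estimateRelativeTwist(rep(fw * 5, 4),
                                 fw * sqrt(25 + c(36, 49, 64, 81)),
                                 nmReference = mean(raws))$relative
    expect_equal(mean(rel), 1, tolerance = 1e-12)
    expect_error(estimateRelativeTwist(10, 12, nmReference = 0),
                 "positive")
})

test_that("segmented azimuthal profiles recover the arc dispersion", {
    cache <- synthCache(); g <- synthGeometry()
    sc <- scatterScene(fibrilSigma = 10, twistSigma = 0,
                       preferredOrientation = 90,
                       intermolAmplitude = 0, poissonNoise = FALSE)
    pat <- generateScatterPattern(sc, g, maps = cache$maps)
    prof <- azimuthalPeakProfile(pat, g, c(0.24, 0.32),
                                 segIndex = cache$segD)
    res <- profileFWHM(prof)
    expect_equal(res$fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 1)
    expect_equal(res$orientation, 90, tolerance = 0.5)
})

test_that("segment signals partition the full-circle net total", {
    cache <- synthCache(); g <- synthGeometry()
    maps <- cache$maps
    c0 <- 40
    pat <- matrix(c0, 2000, 2000)
    ring <- which(maps$q > 0.26 & maps$q < 0.30 & !maps$beamstop)
    h <- 25
    pat[ring] <- c0 + h
    pat[maps$beamstop] <- NA
    prof <- azimuthalPeakProfile(pat, g, c(0.24, 0.32),
                                 segIndex = cache$segD)
    total <- sum(signalValues(prof), na.rm = TRUE)
    reference <- (h / c0) * length(ring)
    expect_equal(total, reference, tolerance = 1e-6)
    expect_identical(sum(prof@missing), 0L)
})

test_that("isotropic rings give flat azimuthal profiles and pure
           background gives a null one", {
    cache <- synthCache(); g <- synthGeometry()
    maps <- cache$maps
    ringI <- 10 * maps$q^-4 +
        3000 * exp(-(maps$q - 0.28)^2 / (2 * 0.012^2))
    ringI[maps$beamstop] <- NA
    ringP <- azimuthalPeakProfile(ringI, g, c(0.24, 0.32),
                                  segIndex = cache$segD)
    s <- signalValues(ringP)
    expect_lt(stats::sd(s, na.rm = TRUE) / mean(s, na.rm = TRUE), 0.02)
    porod <- 10 * maps$q^-4
    porod[maps$beamstop] <- NA
    nullP <- azimuthalPeakProfile(porod, g, c(0.24, 0.32),
                                  segIndex = cache$segD)
    expect_lt(max(abs(signalValues(nullP)), na.rm = TRUE),
              0.01 * mean(s, na.rm = TRUE))
})

test_that("patterns failing the signal gate are skipped with a flag", {
    cache <- synthCache(); g <- synthGeometry()
    blank <- matrix(NA_real_, 2000, 2000)
    m <- reducePattern(blank, g, cache = cache)
    expect_true(is.na(dPeriod(m)))
    expect_true(is.na(intermolSpacing(m)))
    expect_identical(m@flags, "low_signal")
})

test_that("map reduction matches streaming layout reduction", {
    cache <- synthCache(); g <- synthGeometry()
    scenes <- regionScatterScenes()
    layout <- regionBandLayout(1, 3, scenes = scenes)
    map <- generateScatterMap(layout, g, maps = cache$maps)
    a <- as.data.frame(reduceScan(map, cache = cache))
    b <- as.data.frame(reduceLayout(layout, g, cache = cache))
    expect_equal(a$d_period_nm, b$d_period_nm)
    expect_equal(a$intermol_spacing_nm, b$intermol_spacing_nm)
    expect_equal(a$relative_twist, b$relative_twist)
    ## NM-normalized twist: the reference region averages to 1
    expect_equal(mean(a$relative_twist[a$region == "NM"]), 1)
})

test_that("horizontal binning keeps counts, totals and centers", {
    g <- smallGeometry(); maps <- smallMaps()
    scenes <- regionScatterScenes(poissonNoise = TRUE, exposure = 5)
    layout <- regionBandLayout(2, 5, scenes = scenes)
    map <- generateScatterMap(layout, g, maps = maps)
    expect_error(binScanHorizontal(map, 0), "positive integer")
    expect_identical(binScanHorizontal(map, 1), map)
    b2 <- binScanHorizontal(map, 2)
    ## floor(5 / 2) = 2 groups per row, remainder dropped
    expect_identical(length(patternList(b2)), 4L)
    tot <- function(m) sum(vapply(patternList(m), sum, numeric(1),
                                  na.rm = TRUE))
    pos <- scanPositions(map)
    kept <- pos$col %in% 1:4
    totKept <- sum(vapply(patternList(map)[kept], sum, numeric(1),
                          na.rm = TRUE))
    expect_equal(tot(b2), totKept)
    expect_equal(sort(unique(scanPositions(b2)$col)), c(1.5, 3.5))
})
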