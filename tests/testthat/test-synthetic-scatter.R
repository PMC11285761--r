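noiseFree <- function(...) scatterScene(..., poissonNoise = FALSE)

test_that("background-only scene reproduces the pure Porod law", {
    g <- smallGeometry(); maps <- smallMaps()
    sc <- noiseFree(porodAmplitude = 7,
                    dPeriodAmplitudes = c(0, 0, 0),
                    intermolAmplitude = 0, mineralFraction = 0)
    pat <- generateScatterPattern(sc, g, maps = maps)
    unm <- !maps$beamstop
    expect_equal(pat[unm], 7 * maps$q[unm]^-4, tolerance = 1e-12)
    expect_true(all(is.na(pat[maps$beamstop])))
})

test_that("third meridional order sits at Q = 3 * 2*pi / d", {
    cache <- synthCache()
    g <- synthGeometry()
    sc <- noiseFree(dPeriod = 67, porodAmplitude = 0,
                    dPeriodAmplitudes = c(0, 0, 100),
                    intermolAmplitude = 0, fibrilSigma = 5,
                    preferredOrientation = 90)
    pat <- generateScatterPattern(sc, g, maps = cache$maps)
    ## walk up the meridian (az = 90: beam-center column, rows above)
    bc <- 1000L
    col <- pat[1:950, bc]
    qcol <- cache$maps$q[1:950, bc]
    expect_equal(qcol[which.max(col)], 3 * 2 * pi / 67,
                 tolerance = 2 * 0.003851)   # within a pixel
})

test_that("zero fibril dispersion collapses onto two azimuthal bins", {
    g <- smallGeometry(); maps <- smallMaps()
    sc <- noiseFree(fibrilSigma = 0, twistSigma = 0,
                    preferredOrientation = 57.3, porodAmplitude = 0,
                    dPeriodAmplitudes = c(0, 0, 50),
                    intermolAmplitude = 0)
    pat <- generateScatterPattern(sc, g, maps = maps)
    lit <- which(!is.na(pat) & pat > 0)
    expect_gt(length(lit), 0)
    bins <- unique(floor((maps$azimuth[lit] %% 180) / 0.5))
    expect_identical(bins, floor(57.3 / 0.5))
})

test_that("Poisson sampling is seeded and mean-preserving", {
    g <- smallGeometry(); maps <- smallMaps()
    sc <- scatterScene(porodAmplitude = 500, poissonNoise = TRUE,
                       seed = 42L)
    p1 <- generateScatterPattern(sc, g, maps = maps)
    p2 <- generateScatterPattern(sc, g, maps = maps)
    expect_identical(p1, p2)
    p3 <- generateScatterPattern(sc, g, maps = maps, seed = 43L)
    expect_false(identical(p1, p3))
    clean <- generateScatterPattern(
        noiseFree(porodAmplitude = 500), g, maps = maps)
    rel <- abs(sum(p1, na.rm = TRUE) - sum(clean, na.rm = TRUE)) /
        sum(clean, na.rm = TRUE)
    expect_lt(rel, 0.01)
})

test_that("serpentine positions cover the raster exactly once", {
    pos <- serpentinePositions(4, 7, pitch = c(20, 100))
    expect_identical(nrow(pos), 28L)
    expect_false(any(duplicated(pos[, c("row", "col")])))
    expect_setequal(interaction(pos$row, pos$col),
                    interaction(rep(1:4, each = 7), rep(1:7, 4)))
    ## snake order: odd rows ascend, even rows descend
    expect_identical(pos$col[pos$row == 1], 1:7)
    expect_identical(pos$col[pos$row == 2], 7:1)
    expect_equal(diff(sort(unique(pos$x_um))), rep(20, 6))
})

test_that("scatter maps have one deterministic pattern per cell", {
    g <- smallGeometry(); maps <- smallMaps()
    scenes <- regionScatterScenes(poissonNoise = TRUE, exposure = 5)
    layout <- regionBandLayout(3, 2, scenes = scenes)
    m1 <- generateScatterMap(layout, g, maps = maps)
    expect_length(patternList(m1), 6L)
    expect_false(any(duplicated(
        scanPositions(m1)[, c("row", "col")])))
    m2 <- generateScatterMap(layout, g, maps = maps)
    expect_identical(patternList(m1), patternList(m2))
})

test_that("geometry too small for the intermolecular arc is rejected", {
    tiny <- detectorGeometry(sampleDetectorDistance = 150,
                             wavelength = 0.0979, pixelPitch = 75,
                             detectorShape = c(64L, 64L),
                             beamstopRadius = 2)
    expect_error(generateScatterPattern(scatterScene(), tiny),
                 "intermolecular arc")
})

test_that("scene invariants are enforced", {
    expect_error(scatterScene(dPeriod = -1), "dPeriod")
    expect_error(scatterScene(fibrilSigma = -2), "fibrilSigma")
    expect_error(scatterScene(mineralFraction = -0.1), "mineralFraction")
})
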