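test_that("pixelToQ matches a direct trigonometric evaluation", {
    ## 100 px of 100 um = 10 mm off-center at L = 700 mm
    g <- detectorGeometry(sampleDetectorDistance = 700,
                          wavelength = 0.0979, pixelPitch = 100,
                          detectorShape = c(512L, 512L),
                          beamCenter = c(256, 256))
    res <- pixelToQ(g, row = 256, col = 356)
    expect_equal(res$q, 0.916781630604051, tolerance = 1e-9)
    expect_equal(res$azimuth, 0)
    ## beam-center pixel: q = 0, azimuth 0 by convention
    ctr <- pixelToQ(g, 256, 256)
    expect_identical(ctr$q, 0)
    expect_identical(ctr$azimuth, 0)
    expect_error(pixelToQ(g, 0, 10), "outside the detector")
})

test_that("default geometry keeps the usable 0.2-5 window on-detector", {
    g <- detectorGeometry()
    corners <- pixelToQ(g, c(1, 1, 2162, 2162), c(1, 2068, 1, 2068))
    expect_true(all(corners$q > 5))
    lim <- collagenHier:::geometryQLimits(g)
    expect_lt(lim[["qmin"]], 0.2)
})

test_that("azimuth runs counter-clockwise from +x in [0, 360)", {
    g <- smallGeometry()
    expect_equal(pixelToQ(g, 128.5, 200)$azimuth, 0)
    expect_equal(pixelToQ(g, 200, 128.5)$azimuth, 90)
    expect_equal(pixelToQ(g, 128.5, 60)$azimuth, 180)
    expect_equal(pixelToQ(g, 60, 128.5)$azimuth, 270)
})

test_that("geometryMaps agrees with pixelToQ", {
    g <- smallGeometry()
    maps <- smallMaps()
    px <- cbind(row = c(10L, 77L, 200L), col = c(30L, 131L, 250L))
    ref <- pixelToQ(g, px[, "row"], px[, "col"])
    expect_equal(maps$q[px], ref$q)
    expect_equal(maps$azimuth[px], ref$azimuth)
    expect_true(all(maps$beamstop[abs(row(maps$q) - 128.5) < 2 &
                                  abs(col(maps$q) - 128.5) < 2]))
})

test_that("wavevector-spacing conversion round-trips at 1e-12", {
    q <- c(0.094, 0.2813, 2.7, 5)
    expect_equal(spacingToQ(qToSpacing(q)), q, tolerance = 1e-12)
    d <- c(2.13, 2.37, 22.4, 67)
    expect_equal(qToSpacing(spacingToQ(d)), d, tolerance = 1e-12)
})

test_that("photon energy converts to the beamline wavelength", {
    expect_equal(energyToWavelength(12658) * 10, 0.979, tolerance = 6e-4)
})

test_that("geometry validity catches inconsistent definitions", {
    expect_error(detectorGeometry(sampleDetectorDistance = -1),
                 "positive")
    expect_error(detectorGeometry(beamCenter = c(-5, 10)), "inside")
})
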