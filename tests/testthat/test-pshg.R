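test_that("the forward model evaluates the cosine series directly", {
    sc <- pshgScene(shape = c(4L, 4L), a0 = 100, i2 = 0.5, phi2 = 30,
                    i4 = 0, phi4 = 0, shotNoise = FALSE)
    st <- generatePSHGStack(sc)
    k30 <- which(stackAngles(st) == 30)
    k120 <- which(stackAngles(st) == 120)
    expect_equal(unique(as.vector(st@intensities[, , k30])), 150)
    expect_equal(unique(as.vector(st@intensities[, , k120])), 50)
})

test_that("isotropic pixels give identical images at all angles", {
    st <- generatePSHGStack(pshgScene(shape = c(8L, 8L), i2 = 0,
                                      i4 = 0, shotNoise = FALSE))
    for (k in 2:12)
        expect_identical(st@intensities[, , k], st@intensities[, , 1])
})

test_that("stacks are seeded deterministically and clip warnings fire", {
    sc <- pshgScene(shape = c(16L, 16L), shotNoise = TRUE, seed = 9L)
    s1 <- generatePSHGStack(sc)
    s2 <- generatePSHGStack(sc)
    expect_identical(s1@intensities, s2@intensities)
    sc2 <- pshgScene(shape = c(16L, 16L), shotNoise = TRUE, seed = 10L)
    expect_false(identical(generatePSHGStack(sc2)@intensities,
                           s1@intensities))
    expect_warning(
        generatePSHGStack(pshgScene(shape = c(4L, 4L), i2 = 0.8,
                                    i4 = 0.4, shotNoise = FALSE)),
        "clipped")
})

test_that("angle lists must cover a uniform 180-degree period", {
    expect_error(
        generatePSHGStack(pshgScene(shape = c(4L, 4L),
                                    angles = seq(0, 150, 15))),
        "180 deg")
    expect_error(
        generatePSHGStack(pshgScene(shape = c(4L, 4L),
                                    angles = c(0, 15, 40, 60, 90, 120,
                                               150, 180))),
        "uniform")
    expect_error(pshgScene(shape = c(4L, 4L),
                           angles = c(0, 15, 15, 45, 60)),
                 "strictly increasing")
})

test_that("noiseless model stacks are recovered exactly", {
    sc <- pshgScene(shape = c(16L, 16L), a0 = 100, i2 = 0.3,
                    phi2 = 10, i4 = 0.1, phi4 = 40, shotNoise = FALSE)
    fit <- fitCircularHarmonics(generatePSHGStack(sc), mask = TRUE)
    expect_lt(max(abs(a0Map(fit) - 100)), 1e-9)
    expect_lt(max(abs(i2Map(fit) - 0.3)), 1e-9)
    expect_lt(max(abs(phi2Map(fit) - 10)), 1e-9)
    expect_lt(max(abs(i4Map(fit) - 0.1)), 1e-9)
    expect_lt(max(abs(phi4Map(fit) - 40)), 1e-9)
    expect_lt(max(fit@residualMap), 1e-9)
    ## reconstruction at the acquisition angles reproduces the input
    rec <- predictPolarization(fit, seq(0, 165, by = 15))
    expect_equal(rec, generatePSHGStack(sc)@intensities,
                 tolerance = 1e-9)
})

test_that("a single 2-alpha harmonic is read off directly", {
    sc <- pshgScene(shape = c(8L, 8L), a0 = 1, i2 = 0.5, phi2 = 30,
                    i4 = 0, shotNoise = FALSE)
    fit <- fitCircularHarmonics(generatePSHGStack(sc), mask = TRUE)
    expect_equal(mean(i2Map(fit)), 0.5, tolerance = 1e-12)
    expect_equal(mean(phi2Map(fit)), 30, tolerance = 1e-9)
})

test_that("constant stacks fit as isotropic with a0 = the constant", {
    st <- new("PSHGStack",
              intensities = array(7, c(6, 6, 12)),
              angles = seq(0, 165, by = 15), pixelSize = 0.75)
    fit <- fitCircularHarmonics(st, mask = TRUE)
    expect_equal(unique(as.vector(a0Map(fit))), 7)
    expect_lt(max(i2Map(fit)), 1e-12)
    expect_lt(max(i4Map(fit)), 1e-12)
})

test_that("fits are intensity-scale invariant and frame equivariant", {
    sc <- pshgScene(shape = c(12L, 12L), a0 = 80, i2 = 0.35,
                    phi2 = 140, i4 = 0.08, phi4 = 70,
                    shotNoise = FALSE)
    st <- generatePSHGStack(sc)
    fit <- fitCircularHarmonics(st, mask = TRUE)
    ## scale by k: I2, I4, phi unchanged; a0 scales
    k <- 3.7
    st2 <- st; st2@intensities <- st@intensities * k
    fit2 <- fitCircularHarmonics(st2, mask = TRUE)
    expect_equal(i2Map(fit2), i2Map(fit), tolerance = 1e-12)
    expect_equal(i4Map(fit2), i4Map(fit), tolerance = 1e-12)
    expect_equal(phi2Map(fit2), phi2Map(fit), tolerance = 1e-9)
    expect_equal(a0Map(fit2), k * a0Map(fit), tolerance = 1e-12)
    ## shift the polarization frame by delta
    delta <- 20
    st3 <- st; st3@angles <- st@angles + delta
    fit3 <- fitCircularHarmonics(st3, mask = TRUE)
    expect_equal(i2Map(fit3), i2Map(fit), tolerance = 1e-9)
    expect_equal(phi2Map(fit3) %% 180,
                 (phi2Map(fit) + delta) %% 180, tolerance = 1e-9)
    expect_equal(phi4Map(fit3) %% 90,
                 (phi4Map(fit) + delta) %% 90, tolerance = 1e-9)
})

test_that("the intensity threshold masks dim pixels by the stated rule", {
    a0 <- matrix(1, 32, 32)
    a0[8:24, 8:24] <- 1000
    sc <- pshgScene(shape = c(32L, 32L), a0 = a0, i2 = 0.2,
                    shotNoise = FALSE)
    st <- generatePSHGStack(sc)
    keep <- applyIntensityThreshold(st)
    expect_identical(keep, a0 == 1000)
    expect_true(all(applyIntensityThreshold(st, threshold = 0)))
    bright <- generatePSHGStack(pshgScene(shape = c(8L, 8L), a0 = 500,
                                          shotNoise = FALSE))
    expect_true(all(applyIntensityThreshold(bright)))
    expect_error(applyIntensityThreshold(st, threshold = 1e9),
                 "masks every pixel")
})

test_that("zero-intensity pixels are masked out of the fit", {
    arr <- array(100, c(4, 4, 12))
    arr[1, 1, ] <- 0
    st <- new("PSHGStack", intensities = arr,
              angles = seq(0, 165, by = 15), pixelSize = 0.75)
    fit <- fitCircularHarmonics(st, mask = TRUE)
    expect_false(validMask(fit)[1, 1])
    expect_true(all(validMask(fit)[-1]))
    expect_true(is.na(i2Map(fit)[1, 1]))
})

test_that("stacks with too few or duplicated angles are invalid", {
    expect_error(new("PSHGStack", intensities = array(1, c(4, 4, 4)),
                     angles = c(0, 45, 90, 135), pixelSize = 0.75),
                 "at least 5")
    expect_error(new("PSHGStack", intensities = array(1, c(4, 4, 6)),
                     angles = c(0, 30, 60, 90, 120, 180),
                     pixelSize = 0.75),
                 "distinct modulo 180")
})

test_that("region summaries aggregate acquisition means first", {
    mkfit <- function(i2) {
        st <- generatePSHGStack(pshgScene(shape = c(8L, 8L), a0 = 100,
                                          i2 = i2, shotNoise = FALSE))
        fitCircularHarmonics(st, mask = TRUE)
    }
    fits <- lapply(c(0.2, 0.3, 0.4, 0.3), mkfit)
    sm <- summarizeRegions(fits, c("NM", "NM", "NM", "EM"))
    nm <- as.data.frame(sm[sm$region == "NM", ])
    expect_equal(nm$mean_i2, 0.3, tolerance = 1e-9)
    expect_equal(nm$sd_i2, 0.1, tolerance = 1e-9)
    expect_identical(nm$n_acquisitions, 3L)
    em <- as.data.frame(sm[sm$region == "EM", ])
    expect_identical(em$sd_i2, 0)
    expect_true(em$single_acquisition)
    ## an all-dark acquisition is excluded with a message
    dark <- fitCircularHarmonics(
        new("PSHGStack", intensities = array(0, c(4, 4, 12)),
            angles = seq(0, 165, by = 15), pixelSize = 0.75),
        mask = TRUE)
    expect_message(
        sm2 <- summarizeRegions(c(fits, list(dark)),
                                c("NM", "NM", "NM", "EM", "EM")),
        "excluded")
    expect_identical(
        as.data.frame(sm2[sm2$region == "EM", ])$n_acquisitions, 1L)
})
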