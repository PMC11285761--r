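test_that("equal-mean groups give F = 0 and p = 1", {
    v <- rep(c(1, 2, 3), 3)
    g <- rep(c("NM", "EM", "LM"), each = 3)
    res <- regionAnova(v, g)
    expect_equal(res$f_statistic, 0)
    expect_equal(res$p_value, 1)
})

test_that("the F statistic matches a textbook sums-of-squares oracle", {
    v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
    g <- rep(c("a", "b", "c"), each = 3)
    ## oracle by explicit arithmetic
    gm <- mean(v)
    means <- tapply(v, g, mean)
    ssb <- sum(3 * (means - gm)^2)
    ssw <- sum((v - means[g])^2)
    fOracle <- (ssb / 2) / (ssw / 6)
    res <- regionAnova(v, g)
    expect_equal(res$f_statistic, fOracle, tolerance = 1e-10)
    expect_equal(unname(res$df), c(2, 6))
    ## scale invariance
    expect_equal(regionAnova(2 * v, g)$f_statistic, res$f_statistic,
                 tolerance = 1e-12)
})

test_that("degenerate grouped data is rejected with clear errors", {
    expect_error(regionAnova(rep(5, 9), rep(c("a", "b", "c"), 3)),
                 "undefined")
    expect_error(regionAnova(1:5, rep("a", 5)), "2 groups")
    expect_error(regionAnova(c(1, 2, 3, 4), c("a", "a", "a", "b")),
                 ">= 2 values")
})

test_that("identical group pairs get q = 0 and adjusted p = 1", {
    v <- c(1, 2, 3, 1, 2, 3, 5, 6, 7)
    g <- rep(c("a", "b", "c"), each = 3)
    tk <- as.data.frame(tukeyKramer(v, g))
    ab <- tk[tk$group_1 == "a" & tk$group_2 == "b", ]
    expect_equal(ab$q, 0)
    expect_equal(ab$p_adj, 1)
})

test_that("Tukey-Kramer agrees with the reference implementation", {
    set.seed(11)
    v <- c(rnorm(8, 0), rnorm(12, 0.8), rnorm(10, 1.6))
    g <- rep(c("NM", "EM", "LM"), c(8, 12, 10))
    tk <- as.data.frame(tukeyKramer(v, g))
    ref <- TukeyHSD(aov(v ~ factor(g)))[[1]]
    for (i in seq_len(nrow(tk))) {
        key1 <- paste(tk$group_1[i], tk$group_2[i], sep = "-")
        key2 <- paste(tk$group_2[i], tk$group_1[i], sep = "-")
        p <- if (key1 %in% rownames(ref)) ref[key1, "p adj"]
             else ref[key2, "p adj"]
        expect_equal(tk$p_adj[i], p, tolerance = 1e-6)
    }
})

test_that("adjusted p never undercuts the unadjusted pooled t-test", {
    set.seed(21)
    for (rep_i in 1:20) {
        v <- rnorm(24, rep(c(0, 0.5, 1), each = 8))
        g <- rep(c("a", "b", "c"), each = 8)
        an <- regionAnova(v, g)
        dfw <- unname(an$df["within"])
        tk <- as.data.frame(tukeyKramer(v, g))
        for (i in seq_len(nrow(tk))) {
            ## same error model: pooled MSW, N - k df; q = sqrt(2) |t|
            pt <- 2 * pt(tk$q[i] / sqrt(2), dfw, lower.tail = FALSE)
            expect_gte(tk$p_adj[i] + 1e-12, pt)
        }
    }
})

test_that("relabeling groups permutes the pairwise table", {
    set.seed(5)
    v <- rnorm(30, rep(c(0, 1, 2), each = 10))
    g <- rep(c("NM", "EM", "LM"), each = 10)
    g2 <- c(NM = "LM", EM = "NM", LM = "EM")[g]
    tk1 <- as.data.frame(tukeyKramer(v, g))
    tk2 <- as.data.frame(tukeyKramer(v, g2))
    key <- function(df, a, b) {
        i <- (df$group_1 == a & df$group_2 == b) |
             (df$group_1 == b & df$group_2 == a)
        df$q[i]
    }
    expect_equal(key(tk2, "LM", "NM"), key(tk1, "NM", "EM"))
    expect_equal(key(tk2, "NM", "EM"), key(tk1, "EM", "LM"))
})

test_that("pairs with singleton groups are flagged untestable", {
    v <- c(1, 2, 3, 4, 2.5, 10)
    g <- c("a", "a", "b", "b", "b", "c")
    tk <- as.data.frame(tukeyKramer(v, g))
    withC <- tk$group_1 == "c" | tk$group_2 == "c"
    expect_true(all(tk$untestable[withC]))
    expect_true(all(is.na(tk$q[withC])))
    expect_false(any(tk$untestable[!withC]))
    expect_true(all(is.finite(tk$q[!withC])))
})

test_that("the full comparison report carries both layers", {
    v <- c(rnorm(10, 0, 0.1), rnorm(10, 1, 0.1), rnorm(10, 2, 0.1))
    g <- rep(c("NM", "EM", "LM"), each = 10)
    cmp <- compareRegions(v, g, alpha = 0.05, metric = "demo")
    expect_identical(cmp$metric, "demo")
    expect_identical(nrow(cmp$pairwise), 3L)
    expect_true(all(cmp$pairwise$significant))
    expect_lt(cmp$anova$p_value, 1e-10)
})
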