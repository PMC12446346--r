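test_that("all-positive differences give the extreme two-sided p", {
    expect_equal(pairedWilcoxon(1:11, rep(0, 11))$p.value, 2 / 2^11)
    expect_equal(pairedWilcoxon(1:10, rep(0, 10))$p.value, 2 / 2^10)
    expect_equal(pairedWilcoxon(1:11, rep(0, 11))$p.value, 9.765625e-4)
})

test_that("the exact p matches full enumeration for n <= 12", {
    set.seed(123)
    for (i in 1:20) {
        n <- sample(5:12, 1L)
        d <- round(rnorm(n, 0.3), 2)
        d <- d[d != 0]
        if (length(d) < 5L) next
        expect_equal(pairedWilcoxon(d)$p.value, enumWilcoxon(d),
                     tolerance = 1e-12, label = paste("rep", i))
    }
})

test_that("the exact p agrees with the reference test when ties are absent", {
    set.seed(7)
    for (i in 1:10) {
        d <- rnorm(10)
        expect_equal(pairedWilcoxon(d)$p.value,
                     suppressWarnings(stats::wilcox.test(d,
                         exact = TRUE)$p.value),
                     tolerance = 1e-12)
    }
})

test_that("a symmetric difference pattern is maximally non-significant", {
    d <- c(1, -1, 2, -2, 3, -3)
    expect_equal(pairedWilcoxon(d)$p.value, 1)
})

test_that("degenerate Wilcoxon inputs are errors", {
    expect_error(pairedWilcoxon(rep(0, 10)), "zero")
    expect_error(pairedWilcoxon(1:3), "at least 5")
})

test_that("zeros are dropped and ties mid-ranked", {
    d <- c(0, 0, 2, 2, -2, 3, 3)
    res <- pairedWilcoxon(d)
    expect_equal(res$n, 5L)
    ## statistic: ranks of |d| = (2,2,2,4.5,4.5) -> positives 2+2+4.5+4.5
    expect_equal(res$statistic, 13)
})

test_that("large samples switch to the documented normal approximation", {
    set.seed(9)
    d <- rnorm(40, 0.2)
    res <- pairedWilcoxon(d)
    expect_equal(res$method, "normal approximation")
    ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                               correct = TRUE)$p.value)
    expect_equal(res$p.value, ref, tolerance = 1e-9)
})

test_that("bootstrap mean/SE behave on degenerate and two-value inputs", {
    expect_equal(unname(bootstrapMeanSE(rep(3, 5), 200L, 1L)[["se"]]), 0)
    ## two values {0, 1}: resampled means take values 0, .5, 1 with
    ## probabilities 1/4, 1/2, 1/4 -> mean .5, sd sqrt(1/8)
    b <- bootstrapMeanSE(c(0, 1), nBoot = 20000L, seed = 2L)
    expect_equal(unname(b[["mean"]]), 0.5, tolerance = 0.02)
    expect_equal(unname(b[["se"]]), sqrt(1 / 8), tolerance = 0.05)
    expect_identical(bootstrapMeanSE(c(0, 1), 100L, 5L),
                     bootstrapMeanSE(c(0, 1), 100L, 5L))
    expect_error(bootstrapMeanSE(3), "at least 2")
})

test_that("a 1x1 grid equals a direct single run", {
    ph <- smallPhantom(seed = 31L, nCells = 150L)
    cells <- ph$truth$cells
    cells$cell.marker.max <- cells$marker_value
    res <- runSensitivityGrid(list(img = ph$image), list(img = cells),
                              sigmas = 4, thresholds = 12000,
                              feature = "cell.marker.max", nBoot = 50L)
    mask <- buildStromaMask(ph$image, 4, 12000)
    direct <- correlationBySide(
        assignCellDistances(cells, signedDistanceMap(mask)),
        "cell.marker.max")
    expect_equal(res$correlations$r,
                 unname(direct[res$correlations$side]))
})

test_that("degenerate grid points are flagged, not fatal", {
    ph <- smallPhantom(seed = 32L, nCells = 120L)
    cells <- ph$truth$cells
    cells$cell.marker.max <- cells$marker_value
    res <- runSensitivityGrid(list(a = ph$image), list(a = cells),
                              sigmas = 2, thresholds = c(12000, 1e6),
                              feature = "cell.marker.max", nBoot = 20L)
    bad <- res$correlations[res$correlations$threshold == 1e6, ]
    expect_true(all(bad$flagged))
    good <- res$correlations[res$correlations$threshold == 12000, ]
    expect_true(all(!good$flagged))
})

test_that("grid results do not depend on image order", {
    phs <- lapply(c(41L, 42L, 43L), function(s) {
        ph <- smallPhantom(seed = s, nCells = 120L)
        cells <- ph$truth$cells
        cells$cell.marker.max <- cells$marker_value
        list(img = ph$image, cells = cells)
    })
    imgs <- lapply(phs, `[[`, "img")
    tabs <- lapply(phs, `[[`, "cells")
    names(imgs) <- names(tabs) <- c("a", "b", "c")
    r1 <- runSensitivityGrid(imgs, tabs, sigmas = 3, thresholds = 12000,
                             feature = "cell.marker.max", nBoot = 20L)
    ord <- c("c", "a", "b")
    r2 <- runSensitivityGrid(imgs[ord], tabs[ord], sigmas = 3,
                             thresholds = 12000,
                             feature = "cell.marker.max", nBoot = 20L)
    m1 <- r1$correlations[order(r1$correlations$image_id,
                                r1$correlations$side), ]
    m2 <- r2$correlations[order(r2$correlations$image_id,
                                r2$correlations$side), ]
    expect_equal(m1$r, m2$r)
    expect_equal(r1$wilcoxon$p.value, r2$wilcoxon$p.value)
})

test_that("a marker decreasing away from the stroma yields negative outside correlations", {
    ## distance effect monotone decreasing outside: r_outside < 0 across grid
    phs <- lapply(c(51L, 52L, 53L), function(s) {
        ph <- generatePhantomImage(phantomConfig(
            imageSize = c(320L, 320L), nCells = 200L, seed = s,
            distanceEffect = function(d) -pmax(d, 0) / 80))
        cells <- ph$truth$cells
        cells$cell.marker.max <- cells$marker_value
        list(img = ph$image, cells = cells)
    })
    imgs <- setNames(lapply(phs, `[[`, "img"), c("a", "b", "c"))
    tabs <- setNames(lapply(phs, `[[`, "cells"), c("a", "b", "c"))
    res <- runSensitivityGrid(imgs, tabs, sigmas = c(2, 4),
                              thresholds = c(10000, 14000),
                              feature = "cell.marker.max", nBoot = 20L)
    outs <- res$correlations[res$correlations$side == "outside", ]
    expect_true(all(outs$r < 0))
    ## the sign pattern is stable across a +-50% parameter perturbation
    expect_true(all(res$summary$median_r_outside < 0))
})
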