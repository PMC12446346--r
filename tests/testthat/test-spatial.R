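test_that("distance bins are half-open and aligned at the border", {
    tab <- data.frame(signed_distance_um = c(-5, 5, 15))
    b <- binByDistance(tab, 10, c(-10, 20))
    expect_equal(b$edges, c(-10, 0, 10, 20))
    expect_equal(b$index, c(1L, 2L, 3L))
    ## d = 0 falls on the outside-stroma side
    b0 <- binByDistance(data.frame(signed_distance_um = 0), 10, c(-10, 10))
    expect_equal(b0$index, 2L)
    ## out-of-range cells are excluded and counted
    b2 <- binByDistance(data.frame(signed_distance_um = c(-50, 5, 500)),
                        10, c(-10, 20))
    expect_equal(b2$nExcluded, 2L)
    expect_error(binByDistance(data.frame(signed_distance_um = 1000),
                               10, c(-10, 10)), "no cells")
})

test_that("constant bins have zero bootstrap SEM", {
    tab <- data.frame(signed_distance_um = c(1, 2, 3),
                      v = c(4, 4, 4))
    p <- spatialProfile(tab, "v", 10, c(0, 10), nBoot = 50L, seed = 1L)
    expect_equal(binMeans(p), 4)
    expect_equal(binSEMs(p), 0)
    expect_equal(binCounts(p), 3L)
})

test_that("bootstrap SEM approaches the CLT closed form", {
    set.seed(55)
    tab <- data.frame(signed_distance_um = runif(10000, 0, 10),
                      v = rnorm(10000))
    p <- spatialProfile(tab, "v", 10, c(0, 10), nBoot = 500L, seed = 9L)
    expect_equal(binSEMs(p), 1 / sqrt(10000), tolerance = 0.15)
})

test_that("profiles are seed-deterministic and order-invariant in cells", {
    set.seed(20)
    tab <- data.frame(signed_distance_um = runif(500, -30, 30),
                      v = rlnorm(500, 2, 0.5))
    p1 <- spatialProfile(tab, "v", 10, c(-30, 30), nBoot = 100L, seed = 3L)
    p2 <- spatialProfile(tab, "v", 10, c(-30, 30), nBoot = 100L, seed = 3L)
    expect_identical(binSEMs(p1), binSEMs(p2))
    shuf <- tab[sample.int(nrow(tab)), ]
    p3 <- spatialProfile(shuf, "v", 10, c(-30, 30), nBoot = 100L, seed = 3L)
    expect_equal(binMeans(p3), binMeans(p1))
    expect_equal(binCounts(p3), binCounts(p1))
})

test_that("bins with a single cell report a mean but no SEM", {
    tab <- data.frame(signed_distance_um = c(5, 15, 16), v = c(2, 3, 5))
    p <- spatialProfile(tab, "v", 10, c(0, 20), nBoot = 50L, seed = 1L)
    expect_equal(binMeans(p), c(2, 4))
    expect_true(is.na(binSEMs(p)[1L]))
    expect_false(is.na(binSEMs(p)[2L]))
})

test_that("a border-peaked phantom puts the profile maximum beside 0", {
    ph <- generatePhantomImage(phantomConfig(nCells = 400L, seed = 21L))
    cells <- ph$truth$cells
    cells$signed_distance_um <- cells$distance_um
    cells$cell.marker.max <- cells$marker_value
    p <- spatialProfile(cells, "cell.marker.max", 10, c(-100, 100),
                        nBoot = 100L, seed = 2L)
    edges <- binEdges(p)
    peak <- which.max(binMeans(p))
    expect_true(edges[peak] == 0 || edges[peak + 1L] == 0)
})

test_that("profile differences propagate errors per the closed form", {
    set.seed(77)
    mk <- function(seed, shift = 0) {
        withr::with_seed(seed, data.frame(
            signed_distance_um = runif(100, 0, 10),
            v = rnorm(100, shift, 2)))
    }
    pa <- spatialProfile(mk(1), "v", 10, c(0, 10), nBoot = 50L, seed = 1L)
    pb <- spatialProfile(mk(2, 1), "v", 10, c(0, 10), nBoot = 50L, seed = 1L)
    d <- profileDifference(pa, pb)
    expect_equal(d$sem, sqrt(pa@sd^2 / 100 + pb@sd^2 / 100))
    ## equal-group closed form: sigma = 2, n = 100 -> sqrt(8/100)
    sd2 <- pa; sd2@sd <- 2; pb2 <- pb; pb2@sd <- 2
    d2 <- profileDifference(sd2, pb2)
    expect_equal(d2$sem, sqrt(8 / 100))
    ## a profile minus itself: zero difference, sqrt(2) x per-profile term
    dself <- profileDifference(pa, pa)
    expect_equal(dself$difference, 0)
    expect_equal(dself$sem, sqrt(2) * pa@sd / sqrt(100))
})

test_that("mismatched bins and empty bins are handled", {
    tab <- data.frame(signed_distance_um = c(5, 15), v = c(1, 2))
    pa <- spatialProfile(tab, "v", 10, c(0, 20), nBoot = 10L, seed = 1L)
    pb <- spatialProfile(tab, "v", 10, c(0, 30), nBoot = 10L, seed = 1L)
    expect_error(profileDifference(pa, pb), "different edges")
    tab2 <- data.frame(signed_distance_um = c(5, 25, 26), v = c(1, 2, 3))
    pc <- spatialProfile(tab2, "v", 10, c(0, 30), nBoot = 10L, seed = 1L)
    pd <- spatialProfile(tab2, "v", 10, c(0, 30), nBoot = 10L, seed = 1L)
    d <- profileDifference(pc, pd)
    expect_true(is.na(d$difference[2L]))   # empty middle bin
})

test_that("side-wise correlations match the explicit sum formula", {
    tab <- data.frame(signed_distance_um = c(1, 2, 3, -1, -2, -3),
                      v = c(2, 4, 6, 3, 4, 5))
    r <- correlationBySide(tab, "v")
    expect_equal(unname(r[["outside"]]), 1)
    expect_equal(unname(r[["inside"]]), -1)

    set.seed(88)
    tab2 <- data.frame(signed_distance_um = rnorm(200, 0, 30),
                       v = rlnorm(200, 2, 0.5))
    r2 <- correlationBySide(tab2, "v")
    eq1 <- function(I, d) {
        sum((I - mean(I)) * (d - mean(d))) /
            sqrt(sum((I - mean(I))^2) * sum((d - mean(d))^2))
    }
    out <- tab2$signed_distance_um >= 0
    expect_equal(unname(r2[["outside"]]),
                 eq1(tab2$v[out], tab2$signed_distance_um[out]))
    expect_equal(unname(r2[["inside"]]),
                 eq1(tab2$v[!out], tab2$signed_distance_um[!out]))
    ## r is within [-1, 1] and invariant under affine rescaling of I
    tab3 <- tab2; tab3$v <- 100 + 7 * tab3$v
    expect_equal(correlationBySide(tab3, "v"), r2)
    expect_true(all(abs(r2) <= 1))
})

test_that("degenerate sides are flagged undefined", {
    tab <- data.frame(signed_distance_um = c(1, 2, 3), v = c(5, 5, 5))
    r <- correlationBySide(tab, "v")
    expect_true(is.na(r[["outside"]]))
    expect_true(is.na(r[["inside"]]))   # no inside cells at all
})

test_that("profiles export to CSV with counts", {
    tab <- data.frame(signed_distance_um = c(5, 15, 16), v = c(2, 3, 5))
    p <- spatialProfile(tab, "v", 10, c(0, 20), nBoot = 10L, seed = 1L)
    path <- withr::local_tempfile(fileext = ".csv")
    writeProfile(p, path)
    back <- read.csv(path)
    expect_equal(back$n, c(1L, 2L))
    expect_equal(back$bin_left, c(0, 10))
})
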