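test_that("non-touching phantom nuclei are all recovered near their truth", {
    ph <- generatePhantomImage(phantomConfig(nCells = 300L, seed = 7L))
    nuc <- segmentNuclei(getChannel(ph$image, "dapi"))
    expect_equal(max(nuc), 300L)
    tab <- extractFeatures(ph$image, nuc)
    d2 <- outer(tab$centroid_x_um, ph$truth$cells$centroid_x_um, "-")^2 +
          outer(tab$centroid_y_um, ph$truth$cells$centroid_y_um, "-")^2
    nn <- sqrt(apply(d2, 1, min))
    expect_lt(max(nn), pixelSize(ph$image))   # centroids within one pixel
})

test_that("touching nuclei with distinct maxima are split by the watershed", {
    img <- matrix(0, 48, 48)
    for (ctr in list(c(24, 18), c(24, 31))) {
        d2 <- outer((seq_len(48) - ctr[1L])^2, (seq_len(48) - ctr[2L])^2, "+")
        img[d2 <= 8^2] <- 30000
    }
    lab <- segmentNuclei(img, sigma = 1, threshold = 15000)
    expect_equal(max(lab), 2L)
})

test_that("a blank DAPI image yields no nuclei and a warning", {
    expect_warning(lab <- segmentNuclei(matrix(0, 32, 32)), "blank")
    expect_equal(max(lab), 0L)
})

test_that("isolated-cell expansion reproduces disk geometry", {
    mask <- matrix(0L, 64, 64)
    d2 <- outer((seq_len(64) - 32)^2, (seq_len(64) - 32)^2, "+")
    mask[d2 <= 10^2] <- 1L
    ex <- expandCells(mask, radiusUm = 5, pixelSize = 1)
    ## cell should be a disk of radius ~15 px (+- 1 px discretisation)
    areaLo <- sum(d2 <= 14^2); areaHi <- sum(d2 <= 16^2)
    expect_gte(sum(ex$cell == 1L), areaLo)
    expect_lte(sum(ex$cell == 1L), areaHi)
    expect_identical(ex$cytoplasm > 0L, ex$cell > 0L & mask == 0L)
})

test_that("contested expansion pixels match the brute-force partition", {
    mask <- matrix(0L, 40, 40)
    mask[18:22, 8:12] <- 1L     # two square nuclei 12 px apart (col gap)
    mask[18:22, 25:29] <- 2L
    ex <- expandCells(mask, radiusUm = 5, pixelSize = 1)
    expect_identical(ex$cell, bruteExpand(mask, 5))
    ## no pixel belongs to both; boundary is at equidistance
    expect_true(all(ex$cell[, 1:18][ex$cell[, 1:18] > 0] == 1L))
    expect_true(all(ex$cell[, 19:40][ex$cell[, 19:40] > 0] == 2L))

    ## randomised nuclei configurations against brute force
    set.seed(31)
    for (i in 1:3) {
        m <- matrix(0L, 30, 30)
        ctrs <- cbind(sample(5:25, 4), sample(5:25, 4))
        for (k in 1:4) {
            rr <- pmax(1, ctrs[k, 1] + (-2:2)); cc <- pmax(1, ctrs[k, 2] + (-2:2))
            m[rr, cc] <- k
        }
        ex2 <- expandCells(m, radiusUm = 4, pixelSize = 1)
        expect_identical(ex2$cell, bruteExpand(m, 4))
    }
})

test_that("expansion is monotone in the radius", {
    ph <- smallPhantom(seed = 9L, nCells = 60L)
    nuc <- segmentNuclei(getChannel(ph$image, "dapi"))
    ps <- pixelSize(ph$image)
    small <- expandCells(nuc, 3, ps)
    large <- expandCells(nuc, 7, ps)
    for (k in seq_len(max(nuc)))
        expect_true(all(which(small$cell == k) %in% which(large$cell == k) |
                        large$cell[small$cell == k] > 0L))
    expect_true(all(large$cell[small$cell > 0L] > 0L))
})

test_that("a sub-pixel radius warns about empty cytoplasm", {
    mask <- matrix(0L, 10, 10); mask[5, 5] <- 1L
    expect_warning(ex <- expandCells(mask, radiusUm = 0.4, pixelSize = 1),
                   "below one pixel")
    expect_equal(sum(ex$cytoplasm > 0L), 0L)
})

test_that("compartments partition each cell", {
    ph <- smallPhantom(seed = 4L, nCells = 80L)
    nuc <- segmentNuclei(getChannel(ph$image, "dapi"))
    ex <- expandCells(nuc, 5, pixelSize(ph$image))
    expect_true(all((nuc > 0L) + (ex$cytoplasm > 0L) <= 1L)) # disjoint
    expect_identical((ex$cell > 0L), (nuc > 0L) | (ex$cytoplasm > 0L))
    for (k in unique(nuc[nuc > 0L]))
        expect_identical(which(ex$cell == k),
                         sort(c(which(nuc == k), which(ex$cytoplasm == k))))
})

test_that("feature statistics match direct arithmetic and brute force", {
    ## constructed 4-pixel nucleus with values {1, 2, 3, 10}
    img <- matrix(0, 8, 8)
    nuc <- matrix(0L, 8, 8)
    nuc[3, 3:6] <- 1L
    img[3, 3:6] <- c(1, 2, 3, 10)
    mci <- new("MultiChannelImage", channels = list(marker = img),
               pixelSize = 2, imageId = "toy")
    tab <- extractFeatures(mci, nuc)
    expect_equal(tab$nucleus.marker.max, 10)
    expect_equal(tab$nucleus.marker.median, 2.5)
    expect_equal(tab$nucleus.marker.mean, 4)
    expect_equal(tab$nucleus.marker.min, 1)
    expect_equal(tab$nucleus_area_um2, 4 * 2^2)
    expect_equal(tab$centroid_x_um, (mean(3:6) - 0.5) * 2)
    expect_equal(tab$centroid_y_um, (3 - 0.5) * 2)

    ## uniform channel: all statistics collapse to the constant
    img2 <- matrix(7, 8, 8)
    mci2 <- new("MultiChannelImage", channels = list(m = img2),
                pixelSize = 1, imageId = "u")
    tab2 <- extractFeatures(mci2, nuc)
    expect_equal(tab2$nucleus.m.mean, 7)
    expect_equal(tab2$nucleus.m.sd, 0)

    ## brute-force per-pixel loop on a random small image
    set.seed(12)
    img3 <- matrix(runif(64 * 64) * 1000, 64, 64)
    lab3 <- matrix(0L, 64, 64)
    lab3[10:20, 10:20] <- 1L
    lab3[40:50, 30:45] <- 2L
    mci3 <- new("MultiChannelImage", channels = list(m = img3),
                pixelSize = 0.5, imageId = "r")
    tab3 <- extractFeatures(mci3, lab3)
    for (k in 1:2) {
        px <- img3[lab3 == k]
        expect_equal(tab3$nucleus.m.mean[k], mean(px))
        expect_equal(tab3$nucleus.m.median[k], median(px))
        expect_equal(tab3$nucleus.m.sd[k], sd(px))
        expect_equal(tab3$nucleus.m.max[k], max(px))
        expect_equal(tab3$nucleus.m.min[k], min(px))
    }
})

test_that("per-cell marker maxima track the generating draws", {
    ph <- smallPhantom(seed = 15L, nCells = 100L)
    nuc <- segmentNuclei(getChannel(ph$image, "dapi"))
    tab <- extractFeatures(ph$image, nuc)
    d2 <- outer(tab$centroid_x_um, ph$truth$cells$centroid_x_um, "-")^2 +
          outer(tab$centroid_y_um, ph$truth$cells$centroid_y_um, "-")^2
    nn <- apply(d2, 1, which.min)
    relerr <- abs(tab$nucleus.marker.max - ph$truth$cells$marker_value[nn]) /
        ph$truth$cells$marker_value[nn]
    expect_lt(median(relerr), 0.01)   # quantisation only
})

test_that("nuclear-area filter matches a brute-force percentile filter", {
    set.seed(8)
    n <- 1000L
    cells <- data.frame(image_id = "a", cell_id = seq_len(n),
                        nucleus_area_um2 = rgamma(n, 20, 0.5))
    kept <- suppressMessages(filterByNuclearArea(cells))
    q <- quantile(cells$nucleus_area_um2, c(0.05, 0.99), type = 7)
    expected <- cells[cells$nucleus_area_um2 >= q[[1L]] &
                      cells$nucleus_area_um2 <= q[[2L]], ]
    expect_identical(kept$cell_id, expected$cell_id)
    ## filtering is per image, not pooled
    cells2 <- cells; cells2$image_id <- "b"
    cells2$nucleus_area_um2 <- cells2$nucleus_area_um2 * 10
    both <- suppressMessages(filterByNuclearArea(rbind(cells, cells2)))
    expect_equal(sum(both$image_id == "a"), nrow(expected))
    expect_equal(sum(both$image_id == "b"), nrow(expected))
})

test_that("degenerate and identity filters keep everything", {
    cells <- data.frame(image_id = "a", cell_id = 1:10,
                        nucleus_area_um2 = rep(25, 10))
    expect_equal(nrow(suppressMessages(filterByNuclearArea(cells))), 10L)
    set.seed(3)
    cells2 <- data.frame(image_id = "a", cell_id = 1:50,
                         nucleus_area_um2 = runif(50, 10, 60))
    expect_equal(nrow(suppressMessages(
        filterByNuclearArea(cells2, lowPct = 0, highPct = 100))), 50L)
})

test_that("label masks import from TIFF and GeoJSON", {
    lab <- matrix(0L, 16, 16)
    lab[3:5, 3:5] <- 1L; lab[9:12, 9:12] <- 2L
    path <- withr::local_tempfile(fileext = ".tif")
    tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
    expect_identical(importLabels(path, pixelSize = 1), lab)

    gj <- withr::local_tempfile(fileext = ".geojson")
    writeMaskPolygons(lab > 0L, pixelSize = 1, path = gj)
    lab2 <- importLabels(gj, pixelSize = 1, dim = c(16L, 16L))
    expect_equal(max(lab2), 2L)
    expect_identical(lab2 > 0L, lab > 0L)
})
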