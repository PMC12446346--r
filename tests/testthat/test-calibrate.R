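test_that("log-normal parameters are recovered from large samples", {
    set.seed(101)
    fit <- fitDistribution(rlnorm(50000, 2, 0.5))
    expect_equal(fitFamily(fit), "lognormal")
    est <- fitEstimate(fit)
    expect_equal(unname(est[["meanlog"]]), 2, tolerance = 0.02)
    expect_equal(unname(est[["sdlog"]]), 0.5, tolerance = 0.02)
    expect_true(all(!is.na(fitSSE(fit, byFamily = TRUE))))
})

test_that("a restricted pool returns the requested family", {
    set.seed(2)
    fit <- fitDistribution(rlnorm(5000, 2, 0.5), families = "gamma")
    expect_equal(fitFamily(fit), "gamma")
    expect_true(is.finite(fitSSE(fit)))
})

test_that("degenerate inputs are rejected", {
    expect_error(fitDistribution(rep(5, 1000)), "constant")
    expect_error(fitDistribution(runif(50)), "at least 100")
    expect_error(fitDistribution(c(runif(200), -1)), "non-negative")
})

test_that("threshold mapping is the identity on a single fit", {
    set.seed(3)
    fit <- fitDistribution(rlnorm(2000, 2, 0.5))
    for (t in c(3, 8, 20))
        expect_equal(mapThreshold(fit, fit, t), t, tolerance = 1e-12)
})

test_that("mapping between scaled log-normals is multiplication", {
    ## closed form: dst = src shifted by ln(c) in log-location => t_dst = c t
    mk <- function(mu) new("DistributionFit", family = "lognormal",
                           estimate = c(meanlog = mu, sdlog = 0.5),
                           sse = 0, sseByFamily = c(lognormal = 0),
                           estimates = list(), nBins = 200L,
                           nValues = 1000L, valueRange = c(0, 100))
    src <- mk(2); dst <- mk(2 + log(1.7))
    for (t in c(2, 7, 15))
        expect_equal(mapThreshold(src, dst, t), 1.7 * t, tolerance = 1e-9)
})

test_that("round trips return the original threshold for every family pair", {
    set.seed(7)
    x <- rlnorm(3000, 2, 0.4)
    fits <- lapply(distributionFamilies(), function(f)
        fitDistribution(x, families = f))
    t0 <- unname(quantile(x, 0.8))
    for (a in seq_along(fits)) for (b in seq_along(fits)) {
        td <- mapThreshold(fits[[a]], fits[[b]], t0)
        back <- mapThreshold(fits[[b]], fits[[a]], td)
        expect_lt(abs(back - t0) / t0, 1e-6)
        ## the mapped percentile is preserved
        expect_lt(abs(pdistr(fits[[b]], td) - pdistr(fits[[a]], t0)), 1e-9)
    }
})

test_that("threshold mapping is strictly increasing", {
    set.seed(11)
    f1 <- fitDistribution(rlnorm(2000, 2, 0.5), families = "wald")
    f2 <- fitDistribution(rgamma(2000, 4, 0.5), families = "burr")
    ts <- seq(2, 20, length.out = 25)
    mapped <- vapply(ts, function(t) mapThreshold(f1, f2, t), numeric(1L))
    expect_true(all(diff(mapped) > 0))
})

test_that("tail thresholds are unmappable", {
    set.seed(4)
    fit <- fitDistribution(rlnorm(1000, 2, 0.5))
    expect_error(mapThreshold(fit, fit, -1), "unmappable")
})

test_that("propagation recovers multiplicative batch thresholds", {
    scales <- c(1.0, 1.5, 0.8)
    cfg <- phantomConfig(nCells = 20000L, seed = 19L,
                         distanceEffect = function(d) rep(0, length(d)))
    batch <- generateCellTableBatch(cfg, nImages = 3, scales = scales)
    tRef <- batch$truth$thresholds[1L]
    ths <- propagateThresholds(batch$tables, "cell.marker.max",
                               "phantom_1", tRef)
    got <- thresholds(ths)
    expect_equal(got[["phantom_1"]], tRef)
    expect_equal(unname(got), unname(batch$truth$thresholds),
                 tolerance = 0.02)
})

test_that("identical-distribution batches map near the reference", {
    cfg <- phantomConfig(nCells = 20000L, seed = 23L)
    batch <- generateCellTableBatch(cfg, nImages = 3, scales = 1)
    ths <- propagateThresholds(batch$tables, "cell.marker.max",
                               "phantom_1", 9000)
    expect_equal(unname(thresholds(ths)), rep(9000, 3), tolerance = 0.03)
})

test_that("a missing reference image is an error, small images are dropped", {
    cfg <- phantomConfig(nCells = 1000L, seed = 29L)
    batch <- generateCellTableBatch(cfg, nImages = 2)
    expect_error(propagateThresholds(batch$tables, "cell.marker.max",
                                     "nope", 9000), "not found")
    tiny <- batch$tables
    tiny$phantom_2 <- tiny$phantom_2[1:50, ]
    expect_warning(ths <- propagateThresholds(tiny, "cell.marker.max",
                                              "phantom_1", 9000), "<100")
    expect_length(thresholds(ths), 1L)
})

test_that("the top-N% threshold matches order statistics", {
    th <- percentileThreshold(1:1000, 0.10)
    expect_equal(th, 900.1)
    expect_equal(sum(1:1000 > th), 100L)
    ## brute-force linear interpolation between order statistics
    set.seed(5)
    x <- runif(777) * 100
    xs <- sort(x)
    h <- (777 - 1) * 0.75 + 1
    expect_equal(percentileThreshold(x, 0.25),
                 xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)]),
                 tolerance = 1e-12)
    ## near-total fraction approaches the minimum
    expect_lt(percentileThreshold(x, 0.999), sort(x)[2L])
    ## all-equal values: threshold at the value, strict rule labels none
    expect_equal(percentileThreshold(rep(7, 50), 0.1), 7)
    expect_equal(sum(rep(7, 50) > percentileThreshold(rep(7, 50), 0.1)), 0L)
    expect_error(percentileThreshold(numeric(0), 0.1), "no finite")
    expect_error(percentileThreshold(1:10, 1.2), "between 0 and 1")
})

test_that("fit reports serialise to JSON", {
    set.seed(6)
    fit <- fitDistribution(rlnorm(500, 2, 0.5), families = "lognormal")
    path <- withr::local_tempfile(fileext = ".json")
    writeFitReport(fit, path)
    rep <- jsonlite::read_json(path)
    expect_equal(rep$family, "lognormal")
    expect_equal(rep$n_bins, 200L)
})
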