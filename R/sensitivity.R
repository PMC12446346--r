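#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired data.  Zero differences are
#' dropped before ranking and tied absolute differences receive mid-ranks.
#' For up to \code{exactMax} (default 25) non-zero pairs the null
#' distribution of the rank sum is computed exactly by enumerating all sign
#' assignments (a convolution over the doubled mid-ranks, so ties are
#' handled exactly); beyond that a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y paired measurement vectors, or \code{x} alone as the vector
#'   of differences.
#' @param exactMax largest number of non-zero pairs for which the exact
#'   null is enumerated.
#' @return list with \code{p.value}, \code{statistic} (rank sum of positive
#'   differences), \code{n} (non-zero pairs) and \code{method}.
#' @export
#' @examples
#' pairedWilcoxon(1:11, rep(0, 11))$p.value   # 2 / 2^11
pairedWilcoxon <- function(x, y = NULL, exactMax = 25L) {
    d <- if (is.null(y)) x else x - y
    d <- d[is.finite(d)]
    if (length(d) < 5L) stop("need at least 5 pairs")
    d <- d[d != 0]
    if (length(d) == 0L)
        stop("all differences are zero: the test statistic is undefined")
    n <- length(d)
    r <- rank(abs(d), ties.method = "average")
    V <- sum(r[d > 0])
    if (n <= exactMax) {
        ## exact null by convolution over 2r (integers even with mid-ranks):
        ## pmf[w+1] = P(2W = w) under independent random signs
        r2 <- as.integer(round(2 * r))
        total <- sum(r2)
        pmf <- numeric(total + 1L)
        pmf[1L] <- 1
        for (ri in r2) {
            shifted <- c(numeric(ri), pmf[seq_len(total + 1L - ri)])
            pmf <- (pmf + shifted) / 2
        }
        v2 <- as.integer(round(2 * V))
        pLow <- sum(pmf[seq_len(v2 + 1L)])
        pHigh <- sum(pmf[seq.int(v2 + 1L, total + 1L)])
        p <- min(1, 2 * min(pLow, pHigh))
        method <- "exact"
    } else {
        mu <- n * (n + 1) / 4
        tie <- table(r)
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(tie^3 - tie) / 48
        z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
        p <- min(1, 2 * pnorm(-abs(z)))
        method <- "normal approximation"
    }
    list(p.value = p, statistic = V, n = n, method = method)
}

#' Bootstrap mean and standard error across images
#'
#' Resamples image-level values with replacement \code{nBoot} times and
#' reports the mean of the resampled means and their standard deviation —
#' the bootstrap standard error of the across-image mean.
#'
#' @param values numeric vector of per-image summary values (>= 2 images).
#' @param nBoot number of bootstrap iterations.
#' @param seed RNG seed.
#' @return named numeric vector \code{c(mean = ..., se = ...)}.
#' @export
bootstrapMeanSE <- function(values, nBoot = 500L, seed = 1L) {
    values <- values[is.finite(values)]
    if (length(values) < 2L)
        stop("need at least 2 images to bootstrap across images")
    withSeed(seed, {
        bm <- vapply(seq_len(nBoot), function(i)
            mean(values[sample.int(length(values), replace = TRUE)]),
            numeric(1L))
        c(mean = mean(bm), se = sd(bm))
    })
}

#' Sensitivity of spatial correlations to the stroma-mask parameters
#'
#' Grid search over the two parameters that define the stromal mask — the
#' Gaussian smoothing sigma and the fibronectin intensity threshold.  For
#' every (sigma, threshold) combination the mask is rebuilt in each image,
#' signed distances are recomputed, and the Pearson correlation between the
#' marker feature and distance is evaluated separately for cells inside and
#' outside the stroma.  Because both correlations of an image come from the
#' same image under identical conditions, (inside, outside) values are
#' treated as paired; the pairs are pooled across grid points into one
#' paired sample for the overall Wilcoxon signed-rank test, and per-point
#' medians plus an across-image bootstrap summarise each combination.
#'
#' @param images named list of [MultiChannelImage-class] objects (or bare
#'   fibronectin matrices, with \code{pixelSize} supplied).
#' @param cellTables named list of cell tables matching \code{images}
#'   (centroids and the marker feature; distances are recomputed here).
#' @param sigmas,thresholds numeric vectors spanning the grid (sigma in
#'   pixels).
#' @param feature marker feature column.
#' @param channel fibronectin channel name.
#' @param pixelSize micrometres per pixel when images are bare matrices.
#' @param nBoot bootstrap iterations across images per grid point.
#' @param seed RNG seed for the bootstraps.
#' @return list with \code{correlations} (long data.frame: sigma,
#'   threshold, image_id, side, r, flagged), \code{summary} (per grid
#'   point: median r per side, Wilcoxon p across images when >= 5 pairs,
#'   bootstrap mean and SE per side), \code{wilcoxon} (the pooled paired
#'   test over all grid points and images) and \code{nPairs}.
#' @export
runSensitivityGrid <- function(images, cellTables, sigmas, thresholds,
                               feature, channel = "fibronectin",
                               pixelSize = NULL, nBoot = 500L, seed = 1L) {
    if (length(images) < 1L) stop("need at least one image")
    if (length(sigmas) < 1L || length(thresholds) < 1L)
        stop("parameter grids must be non-empty")
    if (is.null(names(images)))
        names(images) <- sprintf("image_%d", seq_along(images))
    rows <- list()
    for (sg in sigmas) for (th in thresholds) {
        for (id in names(images)) {
            img <- images[[id]]
            res <- tryCatch({
                mask <- suppressWarnings(buildStromaMask(
                    img, sigma = sg, threshold = th, channel = channel,
                    pixelSize = pixelSize))
                mm <- maskMatrix(mask)
                if (all(mm) || !any(mm))
                    stop("degenerate mask")
                dm <- signedDistanceMap(mask)
                cells <- assignCellDistances(cellTables[[id]], dm)
                correlationBySide(cells, feature)
            }, error = function(e) c(inside = NA_real_, outside = NA_real_))
            rows[[length(rows) + 1L]] <- data.frame(
                sigma = sg, threshold = th, image_id = id,
                side = c("inside", "outside"), r = as.numeric(res),
                flagged = anyNA(res), stringsAsFactors = FALSE)
        }
    }
    long <- do.call(rbind, rows)

    ## per-grid-point summaries
    key <- interaction(long$sigma, long$threshold, drop = TRUE)
    summ <- do.call(rbind, lapply(split(long, key), function(gr) {
        rin <- gr$r[gr$side == "inside"]
        rout <- gr$r[gr$side == "outside"]
        ok <- is.finite(rin) & is.finite(rout)
        p <- if (sum(ok) >= 5L && any(rin[ok] != rout[ok]))
            pairedWilcoxon(rin[ok], rout[ok])$p.value else NA_real_
        bi <- if (sum(is.finite(rin)) >= 2L)
            bootstrapMeanSE(rin, nBoot, seed) else c(mean = NA, se = NA)
        bo <- if (sum(is.finite(rout)) >= 2L)
            bootstrapMeanSE(rout, nBoot, seed) else c(mean = NA, se = NA)
        data.frame(sigma = gr$sigma[1L], threshold = gr$threshold[1L],
                   median_r_inside = median(rin, na.rm = TRUE),
                   median_r_outside = median(rout, na.rm = TRUE),
                   p_wilcoxon = p,
                   boot_mean_inside = bi[["mean"]], boot_se_inside = bi[["se"]],
                   boot_mean_outside = bo[["mean"]], boot_se_outside = bo[["se"]],
                   n_images = sum(ok), stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL

    ## pooled paired test: all (inside, outside) pairs across grid x images
    w <- reshapePairs(long)
    pooled <- if (nrow(w) >= 5L && any(w$inside != w$outside))
        pairedWilcoxon(w$inside, w$outside) else NULL
    list(correlations = long, summary = summ, wilcoxon = pooled,
         nPairs = nrow(w))
}

## wide (inside, outside) pairs from the long correlation table
reshapePairs <- function(long) {
    ins <- long[long$side == "inside", c("sigma", "threshold", "image_id", "r")]
    outs <- long[long$side == "outside", c("sigma", "threshold", "image_id", "r")]
    m <- merge(ins, outs, by = c("sigma", "threshold", "image_id"),
               suffixes = c(".in", ".out"))
    ok <- is.finite(m$r.in) & is.finite(m$r.out)
    data.frame(inside = m$r.in[ok], outside = m$r.out[ok])
}
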