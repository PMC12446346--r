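#' Build distance bins aligned at the stromal border
#'
#' Uniform half-open bins \code{[a, b)} of fixed width with an edge exactly
#' at 0, so a cell sitting on the border (d = 0) falls on the
#' outside-stroma side.  The default width of 10 um corresponds roughly to
#' one cell diameter.  Cells outside the requested range are excluded and
#' their count reported.
#'
#' @param cells cell table with finite \code{signed_distance_um}.
#' @param binWidthUm bin width in micrometres (> 0).
#' @param rangeUm two-element range in micrometres; the edges are snapped
#'   outward to multiples of the bin width so 0 stays on an edge.
#' @return list with \code{edges} (numeric vector), \code{index} (per-cell
#'   bin index, \code{NA} outside the range) and \code{nExcluded}.
#' @export
#' @examples
#' tab <- data.frame(signed_distance_um = c(-5, 0, 5, 15))
#' binByDistance(tab, 10, c(-10, 20))$index
binByDistance <- function(cells, binWidthUm = 10, rangeUm = c(-100, 300)) {
    if (!"signed_distance_um" %in% names(cells))
        stop("cells carry no 'signed_distance_um'; run assignCellDistances first")
    .assertScalarNumber(binWidthUm, "binWidthUm", positive = TRUE)
    d <- cells$signed_distance_um
    edges <- seq(binWidthUm * floor(rangeUm[1L] / binWidthUm),
                 binWidthUm * ceiling(rangeUm[2L] / binWidthUm),
                 by = binWidthUm)
    inside <- is.finite(d) & d >= edges[1L] & d < edges[length(edges)]
    if (!any(inside)) stop("no cells fall inside the binned range")
    idx <- rep(NA_integer_, length(d))
    idx[inside] <- findInterval(d[inside], edges, rightmost.closed = FALSE)
    list(edges = edges, index = idx, nExcluded = sum(!inside))
}

#' Distance-binned intensity profile with bootstrap SEM
#'
#' Per-bin mean of a marker feature along the signed distance to the stromal
#' border, with the standard error of each bin mean estimated by a seeded
#' bootstrap: cells within the bin are resampled with replacement
#' \code{nBoot} times and the SEM is the standard deviation of the resampled
#' means.  Bins with fewer than two cells report their mean but no SEM.
#'
#' @param cells cell table with \code{signed_distance_um} and the feature.
#' @param feature feature column to profile.
#' @param binWidthUm,rangeUm passed to [binByDistance()]; alternatively pass
#'   a prebuilt \code{bins} object.
#' @param bins optional result of [binByDistance()] on the same cells.
#' @param nBoot number of bootstrap resamples (>= 1).
#' @param seed RNG seed for the bootstrap.
#' @param population descriptive name of the profiled population.
#' @return A [SpatialProfile-class].
#' @export
spatialProfile <- function(cells, feature, binWidthUm = 10,
                           rangeUm = c(-100, 300), bins = NULL,
                           nBoot = 500L, seed = 1L,
                           population = "all") {
    if (!feature %in% names(cells))
        stop(sprintf("feature '%s' not present", feature))
    if (nBoot < 1L) stop("nBoot must be >= 1")
    if (is.null(bins)) bins <- binByDistance(cells, binWidthUm, rangeUm)
    nb <- length(bins$edges) - 1L
    v <- cells[[feature]]
    means <- sds <- sems <- rep(NA_real_, nb)
    counts <- integer(nb)
    withSeed(seed, for (b in seq_len(nb)) {
        x <- v[!is.na(bins$index) & bins$index == b & is.finite(v)]
        counts[b] <- length(x)
        if (length(x) == 0L) next
        means[b] <- mean(x)
        sds[b] <- sd(x)
        if (length(x) >= 2L) {
            bm <- vapply(seq_len(nBoot), function(i)
                mean(x[sample.int(length(x), replace = TRUE)]), numeric(1L))
            sems[b] <- sd(bm)
        }
    })
    new("SpatialProfile", binEdges = bins$edges, mean = means, sem = sems,
        sd = sds, count = counts, featureKey = feature,
        population = population)
}

#' Bin-wise difference of two profiles with propagated error
#'
#' Subtracts two profiles computed on identical bins (e.g. marker-positive
#' minus marker-negative cancer cells) and propagates the per-bin
#' uncertainty as \deqn{SEM = \sqrt{\sigma_a^2/n_a + \sigma_b^2/n_b},} the
#' standard error of a difference of independent bin means.  For equal
#' groups (same sigma and n) this reduces to \eqn{\sqrt{2}\,\sigma/\sqrt{n}}.
#' Bins empty in either profile yield \code{NA}.
#'
#' @param profileA,profileB [SpatialProfile-class] objects on identical bin
#'   edges.
#' @return data.frame with \code{bin_left}, \code{bin_right},
#'   \code{difference}, \code{sem}, \code{n_a}, \code{n_b}.
#' @export
profileDifference <- function(profileA, profileB) {
    stopifnot(is(profileA, "SpatialProfile"), is(profileB, "SpatialProfile"))
    ea <- binEdges(profileA); eb <- binEdges(profileB)
    if (length(ea) != length(eb) || max(abs(ea - eb)) > 1e-9)
        stop("profiles were binned on different edges")
    na <- binCounts(profileA); nb <- binCounts(profileB)
    diff <- binMeans(profileA) - binMeans(profileB)
    sem <- sqrt(profileA@sd^2 / na + profileB@sd^2 / nb)
    empty <- na == 0L | nb == 0L
    diff[empty] <- NA_real_; sem[empty] <- NA_real_
    data.frame(bin_left = ea[-length(ea)], bin_right = ea[-1L],
               difference = diff, sem = sem, n_a = na, n_b = nb)
}

#' Intensity-distance correlation inside and outside the stroma
#'
#' Pearson correlation between a marker feature and the signed distance to
#' the stromal border, computed separately for cells inside the stroma
#' (d < 0) and outside (d >= 0; border cells count as outside, consistent
#' with the half-open binning at 0).  A side with fewer than two cells or
#' zero variance in either variable is flagged \code{NA}.
#'
#' @param cells cell table with \code{signed_distance_um} and the feature.
#' @param feature feature column.
#' @return named numeric vector \code{c(inside = r, outside = r)}.
#' @export
#' @examples
#' tab <- data.frame(signed_distance_um = c(1, 2, 3, -1, -2, -3),
#'                   I = c(2, 4, 6, 5, 4, 3))
#' correlationBySide(tab, "I")
correlationBySide <- function(cells, feature) {
    if (!all(c("signed_distance_um", feature) %in% names(cells)))
        stop("cells need 'signed_distance_um' and the feature column")
    d <- cells$signed_distance_um
    v <- cells[[feature]]
    ok <- is.finite(d) & is.finite(v)
    oneSide <- function(sel) {
        x <- d[sel]; y <- v[sel]
        if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) NA_real_
        else cor(x, y)
    }
    c(inside = oneSide(ok & d < 0), outside = oneSide(ok & d >= 0))
}

#' Export a profile as CSV
#'
#' @param profile a [SpatialProfile-class].
#' @param path output CSV with columns bin_left, bin_right, mean, sem, sd,
#'   n.
#' @return invisibly, the path.
#' @export
writeProfile <- function(profile, path) {
    stopifnot(is(profile, "SpatialProfile"))
    e <- binEdges(profile)
    out <- data.frame(bin_left = e[-length(e)], bin_right = e[-1L],
                      mean = binMeans(profile), sem = binSEMs(profile),
                      sd = profile@sd, n = binCounts(profile))
    for (cn in c("mean", "sem", "sd"))
        out[[cn]] <- sprintf("%.17g", out[[cn]])
    write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Plot a spatial profile
#'
#' Line plot of the per-bin mean with an SEM error band, the standard view
#' of marker intensity against signed distance to the stromal border.
#'
#' @param profile a [SpatialProfile-class].
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, \code{NULL}.
#' @export
plotProfile <- function(profile, ...) {
    e <- binEdges(profile)
    mid <- e[-length(e)] + diff(e) / 2
    m <- binMeans(profile); s <- binSEMs(profile)
    graphics::plot(mid, m, type = "l", xlab = "signed distance to stromal border (um)",
                   ylab = sprintf("mean %s", profile@featureKey), ...)
    ok <- !is.na(m) & !is.na(s)
    graphics::polygon(c(mid[ok], rev(mid[ok])),
                      c((m + s)[ok], rev((m - s)[ok])),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(mid, m)
    graphics::abline(v = 0, lty = 2)
    invisible(NULL)
}
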