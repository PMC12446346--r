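#' Fit a pool of non-negative distributions to an intensity sample
#'
#' Fits every candidate family to the values by maximum likelihood, then
#' scores each fitted density against the density-normalised histogram of the
#' data (fixed number of equal-width bins) by the sum of squared errors at
#' bin centres, and returns the family with minimal SSE.  This
#' MLE-then-SSE-selection scheme is the batch-calibration backbone: the
#' selected fit's CDF and inverse CDF are what [mapThreshold()] uses to
#' carry a classification threshold between images.
#'
#' @param values numeric vector of at least 100 finite, non-negative values
#'   (per-cell feature values, or raw pixel samples).
#' @param nBins number of histogram bins used for SSE scoring (>= 10).
#' @param families subset of [distributionFamilies()] to consider.
#' @return A [DistributionFit-class] object carrying the selected family,
#'   its parameters, the per-family SSE table and the histogram settings.
#' @export
#' @examples
#' set.seed(1)
#' fit <- fitDistribution(rlnorm(5000, meanlog = 2, sdlog = 0.5))
#' fitFamily(fit)
#' fitEstimate(fit)
fitDistribution <- function(values, nBins = 200L,
                            families = distributionFamilies()) {
    values <- values[is.finite(values)]
    if (any(values < 0))
        stop("values must be non-negative")
    if (length(values) < 100L)
        stop("need at least 100 finite values to fit a distribution")
    if (nBins < 10L)
        stop("nBins must be >= 10")
    rng <- range(values)
    if (diff(rng) == 0)
        stop("values are constant; no distribution can be fitted")
    families <- match.arg(families, distributionFamilies(),
                          several.ok = TRUE)

    breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
    width <- diff(breaks[1:2])
    idx <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE),
                     1L), nBins)
    dens <- tabulate(idx, nBins) / (length(values) * width)
    centers <- breaks[-1L] - width / 2

    sses <- setNames(rep(NA_real_, length(families)), families)
    ests <- setNames(vector("list", length(families)), families)
    for (fam in families) {
        reg <- .getFamily(fam)
        est <- tryCatch(reg$fit(values), error = function(e) {
            warning(sprintf("family '%s' failed to fit: %s", fam,
                            conditionMessage(e)), call. = FALSE)
            NULL
        })
        if (is.null(est)) next
        sse <- sum((dens - reg$d(centers, est))^2)
        if (is.finite(sse)) {
            sses[[fam]] <- sse
            ests[[fam]] <- est
        }
    }
    if (all(is.na(sses)))
        stop("no candidate family could be fitted")
    best <- names(which.min(sses))
    new("DistributionFit", family = best, estimate = ests[[best]],
        sse = sses[[best]], sseByFamily = sses, estimates = ests,
        nBins = as.integer(nBins), nValues = length(values),
        valueRange = rng)
}

#' Evaluate a fitted distribution
#'
#' CDF, inverse CDF and density of a [DistributionFit-class] on the original
#' data scale.
#'
#' @param fit a [DistributionFit-class].
#' @param q,x quantiles / evaluation points.
#' @param p probabilities in \code{(0, 1)} (for \code{qdistr}).
#' @return numeric vector.
#' @export
pdistr <- function(fit, q) .getFamily(fit@family)$p(q, fit@estimate)

#' @rdname pdistr
#' @export
qdistr <- function(fit, p) .getFamily(fit@family)$q(p, fit@estimate)

#' @rdname pdistr
#' @export
ddistr <- function(fit, x) .getFamily(fit@family)$d(x, fit@estimate)

#' Map a threshold between two fitted distributions by percentile
#'
#' Percentile mapping: a threshold \eqn{t_i} in the source image's fitted
#' distribution \eqn{F_i} is carried to the destination image by preserving
#' its cumulative probability, \eqn{t_j = F_j^{-1}(F_i(t_i))}.  This is the
#' step that makes an expert's single threshold transferable across images
#' with shifted staining intensity: for purely multiplicative batch shifts
#' of a log-normal signal the mapped threshold is exactly the scaled one.
#'
#' @param fitSrc,fitDst [DistributionFit-class] objects for the source and
#'   destination images.
#' @param t threshold value in the source distribution's support.
#' @return The mapped threshold in the destination image's intensity scale.
#' @export
#' @examples
#' set.seed(1)
#' f1 <- fitDistribution(rlnorm(5000, 2, 0.5), families = "lognormal")
#' f2 <- fitDistribution(1.5 * rlnorm(5000, 2, 0.5), families = "lognormal")
#' mapThreshold(f1, f2, 10)   # close to 15
mapThreshold <- function(fitSrc, fitDst, t) {
    .assertScalarNumber(t, "t")
    p <- pdistr(fitSrc, t)
    if (p <= 0 || p >= 1)
        stop(sprintf(
            "threshold %g sits at CDF %g of the source fit: unmappable tail",
            t, p))
    qdistr(fitDst, p)
}

#' Propagate a reference threshold across a batch of images
#'
#' Fits the chosen feature's distribution in every image of a batch and maps
#' the expert threshold from the reference image to all others by percentile
#' preservation (see [mapThreshold()]).  The reference image maps to itself.
#'
#' @param tables named list of per-image cell tables (data.frames in the
#'   native schema, see [readCellTable()]); names are image ids.
#' @param feature feature column to calibrate on (e.g.
#'   \code{"cell.marker.max"}).
#' @param referenceImage id of the reference image.
#' @param tRef expert threshold chosen in the reference image.
#' @param nBins,families passed to [fitDistribution()].
#' @return A [ThresholdSet-class] with one mapped threshold and one
#'   [DistributionFit-class] per image.  Images with fewer than 100 cells
#'   are excluded with a warning.
#' @export
propagateThresholds <- function(tables, feature, referenceImage, tRef,
                                nBins = 200L,
                                families = distributionFamilies()) {
    if (is.null(names(tables)) || any(names(tables) == ""))
        stop("'tables' must be a named list of per-image cell tables")
    if (!referenceImage %in% names(tables))
        stop(sprintf("reference image '%s' not found in the batch",
                     referenceImage))
    usable <- vapply(tables, function(tab) {
        if (!feature %in% names(tab)) stop(sprintf(
            "feature '%s' missing from a cell table", feature))
        sum(is.finite(tab[[feature]])) >= 100L
    }, logical(1L))
    if (!usable[[referenceImage]])
        stop("reference image has fewer than 100 cells")
    if (any(!usable))
        warning(sprintf("excluding image(s) with <100 cells: %s",
                        paste(names(tables)[!usable], collapse = ", ")),
                call. = FALSE)
    tables <- tables[usable]

    fits <- lapply(tables, function(tab)
        fitDistribution(tab[[feature]], nBins = nBins, families = families))
    ths <- vapply(names(tables), function(id) {
        if (id == referenceImage) tRef
        else mapThreshold(fits[[referenceImage]], fits[[id]], tRef)
    }, numeric(1L))
    new("ThresholdSet", referenceImage = referenceImage,
        referenceThreshold = tRef, feature = feature,
        thresholds = ths, fits = fits)
}

#' Empirical top-N\% threshold
#'
#' Threshold classifying the top \code{topFraction} of values as positive:
#' the empirical \code{1 - topFraction} quantile (linear interpolation,
#' type 7).  Positivity uses the strict rule \code{value > threshold}, so
#' ties at the threshold are labelled negative; on continuous (tie-free)
#' data the positive count equals \code{n * topFraction} whenever that is an
#' attainable order-statistic count (e.g. 100 of 1000 at the top 10\%).
#'
#' @param values numeric vector, length >= 1.
#' @param topFraction fraction of values to classify positive, in (0, 1).
#' @return threshold value.
#' @export
#' @examples
#' percentileThreshold(1:1000, 0.10)   # 900.1; 100 values above
percentileThreshold <- function(values, topFraction) {
    values <- values[is.finite(values)]
    if (length(values) == 0L) stop("no finite values")
    if (!is.numeric(topFraction) || length(topFraction) != 1L ||
        topFraction <= 0 || topFraction >= 1)
        stop("topFraction must lie strictly between 0 and 1")
    quantile(values, 1 - topFraction, type = 7, names = FALSE)
}

#' Serialise a fit report or threshold set to JSON
#'
#' @param object a [DistributionFit-class] or [ThresholdSet-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFitReport <- function(object, path) {
    rep <- if (is(object, "DistributionFit")) {
        list(family = object@family, estimate = as.list(object@estimate),
             sse = object@sse, sse_by_family = as.list(object@sseByFamily),
             n_bins = object@nBins, n_values = object@nValues,
             value_range = object@valueRange)
    } else if (is(object, "ThresholdSet")) {
        list(reference_image = object@referenceImage,
             reference_threshold = object@referenceThreshold,
             feature = object@feature,
             thresholds = as.list(object@thresholds),
             families = lapply(object@fits, function(f) f@family))
    } else stop("unsupported object")
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
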