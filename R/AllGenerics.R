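#' Accessors for stromaSpatial classes
#'
#' Small accessor generics in the Bioconductor style: use these rather than
#' reaching into slots with \code{@}.
#'
#' @param object an object of one of the package's S4 classes.
#' @param ... further arguments for methods.
#' @return The corresponding slot value; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("distanceMatrix", function(object) standardGeneric("distanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("fitFamily", function(object) standardGeneric("fitFamily"))

#' @rdname accessors
#' @export
setGeneric("fitEstimate", function(object) standardGeneric("fitEstimate"))

#' @rdname accessors
#' @export
setGeneric("fitSSE", function(object, ...) standardGeneric("fitSSE"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("binMeans", function(object) standardGeneric("binMeans"))

#' @rdname accessors
#' @export
setGeneric("binSEMs", function(object) standardGeneric("binSEMs"))

#' @rdname accessors
#' @export
setGeneric("agreement", function(object) standardGeneric("agreement"))

## ---- methods ------------------------------------------------------------

#' @rdname accessors
setMethod("pixelSize", "MultiChannelImage", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "StromaMask", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "DistanceMap", function(object) object@pixelSize)

#' @rdname accessors
setMethod("imageId", "MultiChannelImage", function(object) object@imageId)

#' @rdname accessors
setMethod("channelNames", "MultiChannelImage",
    function(object) names(object@channels))

#' @rdname accessors
setMethod("getChannel", "MultiChannelImage", function(object, name) {
    if (!name %in% names(object@channels))
        stop(sprintf("no channel named '%s' (have: %s)", name,
                     paste(names(object@channels), collapse = ", ")))
    object@channels[[name]]
})

#' @rdname accessors
setMethod("maskMatrix", "StromaMask", function(object) object@mask)

#' @rdname accessors
setMethod("distanceMatrix", "DistanceMap", function(object) object@distance)

#' @rdname accessors
setMethod("fitFamily", "DistributionFit", function(object) object@family)

#' @rdname accessors
setMethod("fitEstimate", "DistributionFit", function(object) object@estimate)

#' @rdname accessors
#' @param byFamily if \code{TRUE} return the per-family SSE table instead of
#'   the selected fit's SSE.
setMethod("fitSSE", "DistributionFit", function(object, byFamily = FALSE) {
    if (byFamily) object@sseByFamily else object@sse
})

#' @rdname accessors
setMethod("thresholds", "ThresholdSet", function(object) object@thresholds)

#' @rdname accessors
setMethod("binEdges", "SpatialProfile", function(object) object@binEdges)
#' @rdname accessors
setMethod("binCounts", "SpatialProfile", function(object) object@count)
#' @rdname accessors
setMethod("binMeans", "SpatialProfile", function(object) object@mean)
#' @rdname accessors
setMethod("binSEMs", "SpatialProfile", function(object) object@sem)

#' @rdname accessors
setMethod("agreement", "ConfusionResult", function(object) object@agreement)

## ---- show methods -------------------------------------------------------

setMethod("show", "MultiChannelImage", function(object) {
    d <- dim(object@channels[[1L]])
    cat(sprintf("MultiChannelImage '%s': %d x %d px (%.4g um/px)\n",
                object@imageId, d[1L], d[2L], object@pixelSize))
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "StromaMask", function(object) {
    d <- dim(object@mask)
    cat(sprintf("StromaMask %d x %d px: %.1f%% stromal (sigma=%g px, threshold=%g)\n",
                d[1L], d[2L], 100 * mean(object@mask), object@sigma,
                object@threshold))
})

setMethod("show", "DistanceMap", function(object) {
    r <- range(object@distance)
    cat(sprintf("DistanceMap %d x %d px, signed distance %.1f .. %.1f um\n",
                nrow(object@distance), ncol(object@distance), r[1L], r[2L]))
})

setMethod("show", "DistributionFit", function(object) {
    cat(sprintf("DistributionFit: family '%s' (n=%d, %d bins, SSE=%.4g)\n",
                object@family, object@nValues, object@nBins, object@sse))
    cat("  parameters:",
        paste(sprintf("%s=%.4g", names(object@estimate), object@estimate),
              collapse = ", "), "\n")
})

setMethod("show", "ThresholdSet", function(object) {
    cat(sprintf("ThresholdSet for '%s': reference '%s' at t=%.4g\n",
                object@feature, object@referenceImage,
                object@referenceThreshold))
    print(round(object@thresholds, 4))
})

setMethod("show", "SpatialProfile", function(object) {
    cat(sprintf("SpatialProfile of '%s' (%s): %d bins of %g um on [%g, %g), %d cells\n",
                object@featureKey, object@population,
                length(object@binEdges) - 1L, diff(object@binEdges[1:2]),
                min(object@binEdges), max(object@binEdges),
                sum(object@count)))
})

setMethod("show", "ConfusionResult", function(object) {
    cat(sprintf("ConfusionResult: %d classes, agreement %.1f%%\n",
                length(object@classes), object@agreement))
    print(object@counts)
})

setMethod("show", "PhantomConfig", function(object) {
    cat(sprintf("PhantomConfig: %d x %d px (%.4g um/px), %d cells, '%s' stroma, scale c=%g, seed %d\n",
                object@imageSize[1L], object@imageSize[2L], object@pixelSize,
                object@nCells, object@stromaGeometry, object@batchScale,
                object@seed))
})
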