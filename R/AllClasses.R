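#' @import methods
#' @importFrom stats quantile median sd cor rnorm rlnorm runif rgamma rbeta
#'   dlnorm plnorm qlnorm dgamma pgamma qgamma dbeta pbeta qbeta pnorm
#'   dnorm uniroot optim setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' Multi-channel fluorescence image
#'
#' Container for a set of named, co-registered 2-D intensity channels with a
#' physical pixel size.  Channels are stored as numeric matrices indexed
#' \code{[row = y, col = x]} with the origin at the image top-left; pixel
#' \code{(1,1)} covers the square \code{[0, pixelSize)} x \code{[0, pixelSize)}
#' in micrometre coordinates.  Intensities are non-negative grey levels
#' (16-bit scale, 0--65535, when read from or written to TIFF).
#'
#' @slot channels named list of numeric matrices, one per channel; all the
#'   same dimension.
#' @slot pixelSize physical size of one pixel in micrometres.
#' @slot imageId character identifier for the image.
#'
#' @seealso [readImage()], [generatePhantomImage()]
#' @export
setClass("MultiChannelImage",
    representation(channels = "list", pixelSize = "numeric",
                   imageId = "character"),
    validity = function(object) {
        ch <- object@channels
        if (length(ch) == 0L) return("at least one channel is required")
        if (is.null(names(ch)) || any(names(ch) == ""))
            return("all channels must be named")
        if (anyDuplicated(names(ch))) return("channel names must be unique")
        dims <- lapply(ch, dim)
        if (!all(vapply(ch, is.matrix, logical(1L))))
            return("channels must be 2-D matrices")
        if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
            return("all channels must share identical dimensions")
        if (any(vapply(ch, function(m) any(m < 0, na.rm = TRUE), logical(1L))))
            return("channel intensities must be >= 0")
        if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
            object@pixelSize <= 0)
            return("pixelSize must be a single positive number")
        TRUE
    })

#' Binary stromal mask
#'
#' Result of smoothing a fibronectin channel with a Gaussian filter and
#' thresholding it: \code{TRUE} pixels are stromal.  Carries the parameters
#' it was built from so the segmentation is reproducible.
#'
#' @slot mask logical matrix, \code{TRUE} = stromal.
#' @slot sigma Gaussian smoothing sigma, in pixels (image-native units).
#' @slot threshold intensity threshold applied after smoothing.
#' @slot pixelSize micrometres per pixel.
#'
#' @seealso [buildStromaMask()], [signedDistanceMap()]
#' @export
setClass("StromaMask",
    representation(mask = "matrix", sigma = "numeric", threshold = "numeric",
                   pixelSize = "numeric"),
    validity = function(object) {
        if (!is.logical(object@mask)) return("mask must be a logical matrix")
        if (object@pixelSize <= 0) return("pixelSize must be > 0")
        if (object@sigma < 0) return("sigma must be >= 0")
        TRUE
    })

#' Signed Euclidean distance map
#'
#' Per-pixel signed Euclidean distance to the stromal border, in micrometres:
#' negative inside the stroma, positive outside.  Outside pixels hold the
#' exact Euclidean distance to the nearest stromal pixel; inside pixels hold
#' minus the distance to the nearest non-stromal pixel.
#'
#' @slot distance numeric matrix of signed distances in micrometres.
#' @slot pixelSize micrometres per pixel.
#'
#' @seealso [signedDistanceMap()], [assignCellDistances()]
#' @export
setClass("DistanceMap",
    representation(distance = "matrix", pixelSize = "numeric"),
    validity = function(object) {
        if (!is.numeric(object@distance)) return("distance must be numeric")
        if (object@pixelSize <= 0) return("pixelSize must be > 0")
        TRUE
    })

#' Fitted non-negative intensity distribution
#'
#' A parametric fit to the histogram of a per-cell intensity feature (or raw
#' pixel sample).  Candidate families are fitted by maximum likelihood and
#' the returned family is the one with minimal sum of squared errors between
#' the density-normalised histogram and the fitted density at bin centres.
#' The object carries a CDF / inverse-CDF contract used for percentile
#' mapping of thresholds between images.
#'
#' @slot family selected family, one of \code{"lognormal"}, \code{"wald"},
#'   \code{"burr"}, \code{"beta"}, \code{"gamma"}.
#' @slot estimate named numeric vector of the selected family's parameters.
#' @slot sse sum of squared errors of the selected fit against the
#'   density-normalised histogram.
#' @slot sseByFamily named numeric vector of SSEs for every candidate family
#'   that converged (\code{NA} for families that failed).
#' @slot estimates list of parameter vectors per candidate family.
#' @slot nBins number of histogram bins used for scoring.
#' @slot nValues number of data values fitted.
#' @slot valueRange range of the fitted values.
#'
#' @seealso [fitDistribution()], [mapThreshold()], [pdistr()], [qdistr()]
#' @export
setClass("DistributionFit",
    representation(family = "character", estimate = "numeric",
                   sse = "numeric", sseByFamily = "numeric",
                   estimates = "list", nBins = "integer",
                   nValues = "integer", valueRange = "numeric"),
    validity = function(object) {
        if (length(object@family) != 1L) return("family must be length 1")
        if (!object@family %in% distributionFamilies())
            return(sprintf("unknown family '%s'", object@family))
        if (length(object@valueRange) != 2L) return("valueRange must be length 2")
        TRUE
    })

#' Propagated classification thresholds
#'
#' The result of mapping an expert-chosen threshold from a reference image to
#' every other image of a batch by percentile preservation under fitted
#' distributions: \eqn{t_j = F_j^{-1}(F_i(t_i))}.
#'
#' @slot referenceImage id of the reference image.
#' @slot referenceThreshold the expert threshold in the reference image.
#' @slot feature name of the feature column the thresholds apply to.
#' @slot thresholds named numeric vector of mapped thresholds, one per image
#'   (the reference maps to itself).
#' @slot fits named list of [DistributionFit-class] objects per image.
#'
#' @seealso [propagateThresholds()]
#' @export
setClass("ThresholdSet",
    representation(referenceImage = "character", referenceThreshold = "numeric",
                   feature = "character", thresholds = "numeric",
                   fits = "list"),
    validity = function(object) {
        if (!object@referenceImage %in% names(object@thresholds))
            return("reference image missing from thresholds")
        tref <- object@thresholds[[object@referenceImage]]
        if (abs(tref - object@referenceThreshold) >
            1e-8 * max(1, abs(object@referenceThreshold)))
            return("reference image must map to the reference threshold")
        TRUE
    })

#' Distance-binned intensity profile
#'
#' Means, bootstrap standard errors, standard deviations and cell counts of a
#' marker feature in uniform, half-open signed-distance bins \code{[a, b)}
#' aligned so that 0 (the stromal border) is a bin edge.
#'
#' @slot binEdges numeric vector of bin edges in micrometres (length
#'   \code{nbins + 1}).
#' @slot mean per-bin mean feature value (\code{NA} for empty bins).
#' @slot sem per-bin bootstrap standard error of the mean (\code{NA} when a
#'   bin holds fewer than two cells).
#' @slot sd per-bin standard deviation of the feature.
#' @slot count per-bin number of cells.
#' @slot featureKey feature column the profile summarises.
#' @slot population label for the cell population profiled.
#'
#' @seealso [binByDistance()], [spatialProfile()], [profileDifference()]
#' @export
setClass("SpatialProfile",
    representation(binEdges = "numeric", mean = "numeric", sem = "numeric",
                   sd = "numeric", count = "integer", featureKey = "character",
                   population = "character"),
    validity = function(object) {
        nb <- length(object@binEdges) - 1L
        if (nb < 1L) return("need at least one bin")
        if (any(diff(object@binEdges) <= 0)) return("bin edges must increase")
        w <- diff(object@binEdges)
        if (max(abs(w - w[1L])) > 1e-9 * w[1L]) return("bins must be uniform")
        for (s in c("mean", "sem", "sd"))
            if (length(slot(object, s)) != nb)
                return(sprintf("'%s' must have one entry per bin", s))
        if (length(object@count) != nb) return("'count' must match bins")
        if (any(object@count < 0L)) return("counts must be >= 0")
        TRUE
    })

#' Confusion matrix between two labelings
#'
#' Cross-tabulation of two labelings of the same cells, with the agreement
#' percentage (100 x trace / total).
#'
#' @slot classes character vector of class names (union of both labelings).
#' @slot counts integer matrix; rows = labeling A, columns = labeling B.
#' @slot agreement agreement percentage in \code{[0, 100]}.
#'
#' @seealso [confusionMatrix()]
#' @export
setClass("ConfusionResult",
    representation(classes = "character", counts = "matrix",
                   agreement = "numeric"),
    validity = function(object) {
        if (any(object@counts < 0)) return("counts must be >= 0")
        if (!all(dim(object@counts) == length(object@classes)))
            return("counts must be square on the class set")
        if (object@agreement < 0 || object@agreement > 100)
            return("agreement must lie in [0, 100]")
        TRUE
    })

#' Phantom simulation configuration
#'
#' Parameters of the synthetic-image generator: image geometry, stromal
#' geometry, cell placement, the log-normal marker model with its
#' distance-effect term, the per-image multiplicative batch scale, noise and
#' seed.  See [phantomConfig()] for defaults and units.
#'
#' @slot imageSize integer vector (rows, cols) in pixels.
#' @slot pixelSize micrometres per pixel.
#' @slot stromaGeometry one of \code{"band"}, \code{"annulus"}, \code{"blobs"}.
#' @slot geometryParams named list of geometry parameters (micrometres).
#' @slot nCells number of cells to place.
#' @slot nucleusRadiusMean,nucleusRadiusSd nuclear radius distribution (um).
#' @slot markerMu,markerSigma baseline log-scale location and scale of the
#'   marker intensity.
#' @slot distanceEffect function g(d) added to the log-scale location,
#'   evaluated at the true signed distance in micrometres.
#' @slot batchScale multiplicative intensity scale factor c for this image.
#' @slot noiseSd additive Gaussian noise standard deviation (grey levels).
#' @slot cancerFraction fraction of cells in the cytokeratin-high subset.
#' @slot markerThreshold reference-scale marker threshold defining the
#'   ground-truth positive class (image k uses \code{batchScale * threshold}).
#' @slot seed integer seed; fixed seed gives byte-identical output.
#' @export
setClass("PhantomConfig",
    representation(imageSize = "integer", pixelSize = "numeric",
                   stromaGeometry = "character", geometryParams = "list",
                   nCells = "integer", nucleusRadiusMean = "numeric",
                   nucleusRadiusSd = "numeric", markerMu = "numeric",
                   markerSigma = "numeric", distanceEffect = "function",
                   batchScale = "numeric", noiseSd = "numeric",
                   cancerFraction = "numeric", markerThreshold = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (object@nCells < 0L) return("nCells must be >= 0")
        if (object@markerSigma <= 0) return("markerSigma must be > 0")
        if (any(object@batchScale <= 0)) return("batchScale must be > 0")
        if (object@pixelSize <= 0) return("pixelSize must be > 0")
        if (!object@stromaGeometry %in% c("band", "annulus", "blobs"))
            return("stromaGeometry must be band, annulus or blobs")
        if (object@cancerFraction < 0 || object@cancerFraction > 1)
            return("cancerFraction must lie in [0, 1]")
        TRUE
    })
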