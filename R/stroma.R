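#' Model the stromal region from a fibronectin channel
#'
#' Smooths the fibronectin channel with a Gaussian filter and thresholds it:
#' pixels whose smoothed intensity exceeds the threshold are classified as
#' stromal.  Fibronectin is a secreted extracellular-matrix protein enriched
#' in the stroma, so this binary mask is the working model of the stromal
#' compartment and its boundary is the spatial reference for all
#' distance-based analyses.
#'
#' The smoothing sigma is accepted in image-native pixel units by default
#' (the unit in which such sigmas are usually reported); pass
#' \code{sigmaUnits = "um"} to give it in micrometres instead.
#'
#' @param x a [MultiChannelImage-class] (its \code{channel} is used) or a
#'   numeric intensity matrix.
#' @param sigma Gaussian smoothing sigma, >= 0 (0 disables smoothing).
#' @param threshold intensity threshold on the smoothed channel.
#' @param channel channel name when \code{x} is a [MultiChannelImage-class]
#'   (default \code{"fibronectin"}).
#' @param sigmaUnits \code{"px"} (default) or \code{"um"}.
#' @param pixelSize micrometres per pixel; required when \code{x} is a bare
#'   matrix.
#' @return A [StromaMask-class].  An empty or full mask triggers a warning
#'   (the threshold is outside the smoothed channel's range).
#' @export
#' @examples
#' ch <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
#' m <- buildStromaMask(ch, sigma = 0, threshold = 50, pixelSize = 1)
#' mean(maskMatrix(m))   # half the pixels are stromal
buildStromaMask <- function(x, sigma, threshold, channel = "fibronectin",
                            sigmaUnits = c("px", "um"), pixelSize = NULL) {
    sigmaUnits <- match.arg(sigmaUnits)
    if (is(x, "MultiChannelImage")) {
        mat <- getChannel(x, channel)
        pixelSize <- pixelSize(x)
    } else if (is.matrix(x)) {
        mat <- x
        if (is.null(pixelSize))
            stop("pixelSize is required when 'x' is a matrix")
    } else stop("'x' must be a MultiChannelImage or a matrix")
    .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
    if (sigma < 0) stop("sigma must be >= 0")
    sigmaPx <- if (sigmaUnits == "um") sigma / pixelSize else sigma

    sm <- if (sigmaPx > 0)
        .im2mat(EBImage::gblur(mat, sigma = sigmaPx))
    else mat
    mask <- sm > threshold
    if (!any(mask))
        warning("threshold above the smoothed channel maximum: empty stroma mask",
                call. = FALSE)
    else if (all(mask))
        warning("threshold below the smoothed channel minimum: full stroma mask",
                call. = FALSE)
    new("StromaMask", mask = mask, sigma = sigmaPx, threshold = threshold,
        pixelSize = pixelSize)
}

#' Signed Euclidean distance to the stromal border
#'
#' Computes, for every pixel, the exact Euclidean distance to the nearest
#' opposite-phase pixel, signed by mask membership: outside pixels carry
#' \code{+} the distance to the nearest stromal pixel, inside pixels carry
#' \code{-} the distance to the nearest non-stromal pixel.  Distances are
#' returned in micrometres.  Cells at the stromal interface therefore sit
#' near 0.
#'
#' @param mask a [StromaMask-class], or a logical matrix (then supply
#'   \code{pixelSize}).
#' @param pixelSize micrometres per pixel when \code{mask} is a matrix.
#' @return A [DistanceMap-class].
#' @export
signedDistanceMap <- function(mask, pixelSize = NULL) {
    if (is(mask, "StromaMask")) {
        pixelSize <- pixelSize(mask)
        mask <- maskMatrix(mask)
    }
    if (!is.matrix(mask) || !is.logical(mask))
        stop("'mask' must be a logical matrix or a StromaMask")
    .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
    if (all(mask) || !any(mask))
        stop("mask is empty or full: there is no border to measure from")
    ## EBImage::distmap gives each foreground pixel its exact Euclidean
    ## distance to the nearest background pixel (verified against brute
    ## force); the signed field is the outside EDT minus the inside EDT.
    dOut <- .im2mat(EBImage::distmap(EBImage::Image(1 - mask)))
    dIn <- .im2mat(EBImage::distmap(EBImage::Image(mask * 1)))
    new("DistanceMap", distance = (dOut - dIn) * pixelSize,
        pixelSize = pixelSize)
}

#' Assign signed border distances to cells
#'
#' Samples the signed distance map at the pixel containing each cell's
#' nuclear centroid (nearest-pixel sampling; distances are later binned far
#' more coarsely than a pixel) and stores it in the
#' \code{signed_distance_um} column.
#'
#' @param cells cell table (native schema, with \code{centroid_x_um} /
#'   \code{centroid_y_um}).
#' @param distanceMap a [DistanceMap-class].
#' @return the cell table with \code{signed_distance_um} filled in; cells
#'   whose centroid falls outside the image grid get \code{NA} and
#'   \code{flag_out_of_bounds = TRUE}.
#' @export
assignCellDistances <- function(cells, distanceMap) {
    stopifnot(is(distanceMap, "DistanceMap"))
    if (!all(c("centroid_x_um", "centroid_y_um") %in% names(cells)))
        stop("cell table lacks centroid columns")
    ps <- pixelSize(distanceMap)
    d <- distanceMatrix(distanceMap)
    col <- floor(cells$centroid_x_um / ps) + 1L
    row <- floor(cells$centroid_y_um / ps) + 1L
    inb <- row >= 1L & row <= nrow(d) & col >= 1L & col <= ncol(d) &
        is.finite(row) & is.finite(col)
    out <- rep(NA_real_, nrow(cells))
    out[inb] <- d[cbind(row[inb], col[inb])]
    cells$signed_distance_um <- out
    cells$flag_out_of_bounds <- !inb
    if (any(!inb))
        warning(sprintf("%d cell(s) outside the image grid were flagged",
                        sum(!inb)), call. = FALSE)
    cells
}
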