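#' Segment nuclei from a DAPI channel
#'
#' Classical nucleus segmentation: Gaussian blur, global threshold (Otsu by
#' default, or a fixed value), hole filling, then a distance-transform
#' watershed to split touching nuclei, and removal of objects below a
#' minimum area.  It serves as a pluggable stand-in for neural segmenters;
#' externally computed label masks can be substituted via [importLabels()].
#'
#' @param dapi 2-D non-negative intensity matrix (or a
#'   [MultiChannelImage-class], in which case its \code{"dapi"} channel is
#'   used).
#' @param sigma blur sigma in pixels before thresholding.
#' @param threshold fixed intensity threshold; \code{NULL} (default) selects
#'   it automatically by Otsu's method.
#' @param minAreaPx discard objects smaller than this many pixels.
#' @param watershedTolerance minimum height of an object's highest point
#'   above its merge level for it to count as a separate nucleus.
#' @return integer label matrix (0 = background, k > 0 = nucleus k).  A
#'   blank image yields an all-zero mask with a warning.
#' @export
segmentNuclei <- function(dapi, sigma = 2, threshold = NULL, minAreaPx = 10L,
                          watershedTolerance = 1) {
    if (is(dapi, "MultiChannelImage")) dapi <- getChannel(dapi, "dapi")
    stopifnot(is.matrix(dapi))
    if (all(dapi == dapi[1L])) {
        warning("blank image: no nuclei found", call. = FALSE)
        return(matrix(0L, nrow(dapi), ncol(dapi)))
    }
    sm <- if (sigma > 0) .im2mat(EBImage::gblur(dapi, sigma = sigma))
        else dapi
    if (is.null(threshold)) {
        ## Otsu on the 16-bit grey scale; EBImage::otsu expects [0,1]
        top <- max(sm)
        threshold <- EBImage::otsu(EBImage::Image(sm / top),
                                   range = c(0, 1)) * top
    }
    bin <- sm > threshold
    if (!any(bin)) {
        warning("threshold above image maximum: no nuclei found",
                call. = FALSE)
        return(matrix(0L, nrow(dapi), ncol(dapi)))
    }
    bin <- EBImage::fillHull(EBImage::Image(bin * 1))
    dm <- EBImage::distmap(bin)
    lab <- EBImage::watershed(dm, tolerance = watershedTolerance, ext = 1)
    lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
    ## drop small objects and relabel compactly
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minAreaPx)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    lab
}

#' Import an external label mask
#'
#' Loads a nucleus label mask produced outside the package: either an
#' integer-valued TIFF (e.g. exported from a neural segmenter) or a GeoJSON
#' FeatureCollection of nucleus polygons in micrometre coordinates.
#'
#' @param path path to a \code{.tif}/\code{.tiff} label image or a
#'   \code{.geojson}/\code{.json} polygon file.
#' @param pixelSize micrometres per pixel.
#' @param dim image dimension \code{c(rows, cols)}; required for GeoJSON
#'   input (polygons carry no grid).
#' @return integer label matrix.  Overlapping GeoJSON polygons are an error
#'   (the first overlapping pixel is reported).
#' @export
importLabels <- function(path, pixelSize, dim = NULL) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        raw <- tiff::readTIFF(path)
        lab <- round(raw * 65535)
        if (max(abs(lab - raw * 65535)) > 1e-6)
            stop("label TIFF does not hold integer data")
        return(matrix(as.integer(lab), nrow(raw), ncol(raw)))
    }
    if (ext %in% c("geojson", "json")) {
        if (is.null(dim)) stop("'dim' is required for GeoJSON label input")
        polys <- readMaskPolygons(path)
        lab <- matrix(0L, dim[1L], dim[2L])
        for (k in seq_along(polys)) {
            rings <- lapply(polys[[k]], function(r) r / pixelSize)
            hit <- .rasterizeRings(rings, dim)
            clash <- hit & lab > 0L
            if (any(clash)) {
                idx <- which(clash, arr.ind = TRUE)[1L, ]
                stop(sprintf(
                    "overlapping polygons at pixel (row %d, col %d)",
                    idx[1L], idx[2L]))
            }
            lab[hit] <- k
        }
        return(lab)
    }
    stop(sprintf("unsupported label format '%s'", ext))
}

#' Expand nuclei into whole-cell and cytoplasm masks
#'
#' Approximates whole-cell boundaries by radially expanding every nucleus by
#' a fixed distance (default 5 um).  Where expansions would overlap, each
#' contested pixel is assigned to the nucleus whose boundary is nearest
#' (exact Euclidean distance to the nucleus' pixel set; ties go to the lower
#' label id), so cells never overlap.  The cytoplasm of a cell is its
#' expanded region minus all nuclei.
#'
#' @param labelMask integer nucleus label matrix (from [segmentNuclei()] or
#'   [importLabels()]).
#' @param radiusUm expansion radius in micrometres (> 0).
#' @param pixelSize micrometres per pixel.
#' @return list with integer label matrices \code{cell} (nucleus plus
#'   expansion) and \code{cytoplasm} (expansion only).  A radius below one
#'   pixel warns: cytoplasm may be empty.
#' @export
expandCells <- function(labelMask, radiusUm = 5.0, pixelSize) {
    stopifnot(is.matrix(labelMask))
    .assertScalarNumber(radiusUm, "radiusUm", positive = TRUE)
    .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
    radiusPx <- round(radiusUm / pixelSize)
    if (radiusUm / pixelSize < 1)
        warning("expansion radius is below one pixel: cytoplasm may be empty",
                call. = FALSE)
    nr <- nrow(labelMask); nc <- ncol(labelMask)
    labs <- sort(unique(labelMask[labelMask > 0L]))
    bestDist <- matrix(Inf, nr, nc)
    bestLab <- matrix(0L, nr, nc)
    ## Per-nucleus exact EDT on a padded bounding box; accumulating the
    ## global minimum reproduces the brute-force nearest-nucleus partition.
    ## Strict '<' with ascending labels gives the lower-label tie rule.
    for (k in labs) {
        idx <- which(labelMask == k, arr.ind = TRUE)
        r0 <- max(1L, min(idx[, 1L]) - radiusPx)
        r1 <- min(nr, max(idx[, 1L]) + radiusPx)
        c0 <- max(1L, min(idx[, 2L]) - radiusPx)
        c1 <- min(nc, max(idx[, 2L]) + radiusPx)
        sub <- labelMask[r0:r1, c0:c1, drop = FALSE] == k
        d <- .im2mat(EBImage::distmap(EBImage::Image(1 - sub)))
        upd <- d <= radiusPx & d < bestDist[r0:r1, c0:c1]
        bd <- bestDist[r0:r1, c0:c1]; bl <- bestLab[r0:r1, c0:c1]
        bd[upd] <- d[upd]; bl[upd] <- k
        bestDist[r0:r1, c0:c1] <- bd; bestLab[r0:r1, c0:c1] <- bl
    }
    ## nucleus pixels always belong to their own label
    nucpix <- labelMask > 0L
    bestLab[nucpix] <- labelMask[nucpix]
    cyto <- bestLab
    cyto[nucpix] <- 0L
    list(cell = bestLab, cytoplasm = cyto)
}

#' Extract per-cell, per-compartment intensity features
#'
#' For every cell, channel and subcellular compartment (nucleus, cytoplasm,
#' whole cell) computes the mean, median, min, max and standard deviation of
#' pixel intensities, plus the nuclear centroid and area in micrometre
#' units.  Feature columns follow the frozen native schema
#' \code{<compartment>.<channel>.<statistic>} (see [featureKey()]).
#'
#' @param image a [MultiChannelImage-class].
#' @param nucleusMask integer nucleus label matrix.
#' @param cellMasks list with \code{cell} and \code{cytoplasm} label
#'   matrices, as returned by [expandCells()]; \code{NULL} restricts output
#'   to nuclear features.
#' @return data.frame cell table in the native schema.  Cells with an empty
#'   compartment get \code{NA} statistics and \code{flag_empty_compartment =
#'   TRUE}.
#' @export
extractFeatures <- function(image, nucleusMask, cellMasks = NULL) {
    stopifnot(is(image, "MultiChannelImage"))
    ps <- pixelSize(image)
    labs <- sort(unique(nucleusMask[nucleusMask > 0L]))
    if (length(labs) == 0L)
        return(emptyCellTable())
    nr <- nrow(nucleusMask)

    ## nuclear geometry: centroid of pixel centres, area in um^2
    idx <- which(nucleusMask > 0L)
    lab <- nucleusMask[idx]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    areaPx <- tapply(idx, lab, length)
    cx <- tapply((cols - 0.5) * ps, lab, mean)
    cy <- tapply((rows - 0.5) * ps, lab, mean)

    out <- data.frame(
        image_id = imageId(image),
        cell_id = as.integer(names(areaPx)),
        centroid_x_um = as.numeric(cx),
        centroid_y_um = as.numeric(cy),
        nucleus_area_um2 = as.numeric(areaPx) * ps^2,
        stringsAsFactors = FALSE)

    comps <- list(nucleus = nucleusMask)
    if (!is.null(cellMasks)) {
        comps$cytoplasm <- cellMasks$cytoplasm
        comps$cell <- cellMasks$cell
    }
    stats <- list(mean = mean, median = median, min = min, max = max,
                  sd = sd)
    empty <- rep(FALSE, length(labs))
    for (comp in names(comps)) {
        cm <- comps[[comp]]
        cidx <- which(cm > 0L)
        clab <- factor(cm[cidx], levels = labs)
        present <- labs %in% cm[cidx]
        empty <- empty | !present
        for (chan in channelNames(image)) {
            px <- getChannel(image, chan)[cidx]
            vals <- split(px, clab)
            for (st in names(stats)) {
                v <- vapply(vals, function(p)
                    if (length(p)) stats[[st]](p) else NA_real_, numeric(1L))
                out[[featureKey(comp, chan, st)]] <- as.numeric(v)
            }
        }
    }
    out$flag_empty_compartment <- empty
    if (any(empty))
        warning(sprintf("%d cell(s) have an empty compartment", sum(empty)),
                call. = FALSE)
    rownames(out) <- NULL
    out
}

#' Filter cells by nuclear area percentiles
#'
#' Per-image quality filter: within each image, nuclei strictly smaller than
#' the \code{lowPct}-th percentile or strictly larger than the
#' \code{highPct}-th percentile of nuclear area are discarded (they mostly
#' represent debris, immune cells or fused nuclei).  Percentiles use linear
#' interpolation (type 7); cells exactly at a percentile boundary are kept.
#'
#' @param cells cell table with \code{image_id} and \code{nucleus_area_um2}.
#' @param lowPct,highPct percentile bounds, \code{0 <= lowPct < highPct <=
#'   100}.
#' @return the filtered cell table; the number of discarded cells is
#'   reported via \code{message()}.  An error is raised if nothing survives.
#' @export
filterByNuclearArea <- function(cells, lowPct = 5, highPct = 99) {
    if (nrow(cells) < 2L) stop("need at least 2 cells to filter")
    if (lowPct < 0 || highPct > 100 || lowPct >= highPct)
        stop("require 0 <= lowPct < highPct <= 100")
    keep <- unlist(lapply(split(seq_len(nrow(cells)), cells$image_id),
        function(ii) {
            a <- cells$nucleus_area_um2[ii]
            q <- quantile(a, c(lowPct, highPct) / 100, type = 7,
                          names = FALSE)
            ii[a >= q[1L] & a <= q[2L]]
        }), use.names = FALSE)
    if (length(keep) == 0L)
        stop("nuclear-area filter discarded every cell")
    message(sprintf("nuclear-area filter: discarded %d of %d cells",
                    nrow(cells) - length(keep), nrow(cells)))
    cells[sort(keep), , drop = FALSE]
}
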