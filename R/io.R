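#' Native cell-table schema
#'
#' The package stores per-cell measurements in plain data.frames with a
#' frozen column schema: \code{image_id}, \code{cell_id},
#' \code{centroid_x_um}, \code{centroid_y_um}, \code{nucleus_area_um2},
#' optional \code{signed_distance_um}, feature columns named
#' \code{<compartment>.<channel>.<statistic>} (compartments
#' \code{nucleus}/\code{cytoplasm}/\code{cell}; statistics
#' \code{mean}/\code{median}/\code{min}/\code{max}/\code{sd}) and label
#' columns named \code{label.<name>} holding \code{"positive"} /
#' \code{"negative"}.  Coordinates are micrometres with the origin at the
#' image top-left, x rightward and y downward; pixel \code{(1,1)} spans
#' \code{[0, pixelSize)^2}.
#'
#' @param compartment,channel,statistic components of a feature column name.
#' @return \code{featureKey()} returns the column name;
#'   \code{emptyCellTable()} a zero-row table with the required columns.
#' @export
#' @examples
#' featureKey("cell", "marker", "max")
featureKey <- function(compartment, channel, statistic)
    paste(compartment, channel, statistic, sep = ".")

#' @rdname featureKey
#' @export
emptyCellTable <- function()
    data.frame(image_id = character(0), cell_id = integer(0),
               centroid_x_um = numeric(0), centroid_y_um = numeric(0),
               nucleus_area_um2 = numeric(0), stringsAsFactors = FALSE)

#' Read a multi-channel TIFF image
#'
#' Reads a single- or multi-page TIFF and maps its planes onto the four
#' channel roles of the pipeline (nuclei stain, pan-cytokeratin,
#' fibronectin, marker of interest).  Pixel values are returned on the
#' 16-bit grey-level scale (0--65535).  The pixel size is taken from the
#' TIFF resolution metadata when present and from the
#' \code{pixelSizeUm} argument otherwise.
#'
#' @param path TIFF file with at least as many planes as mapped roles.
#' @param channelMap named integer vector role -> 1-based plane index, e.g.
#'   \code{c(dapi = 1, cytokeratin = 2, fibronectin = 3, marker = 4)}.
#'   Roles must map to distinct planes.
#' @param pixelSizeUm fallback pixel size in micrometres.
#' @param imageId image identifier; defaults to the file name.
#' @return A [MultiChannelImage-class] with one named channel per role.
#' @export
readImage <- function(path,
                      channelMap = c(dapi = 1L, cytokeratin = 2L,
                                     fibronectin = 3L, marker = 4L),
                      pixelSizeUm = 0.3215,
                      imageId = sub("\\.[^.]+$", "", basename(path))) {
    if (is.null(names(channelMap)) || any(names(channelMap) == ""))
        stop("channelMap must be a named vector role -> plane index")
    if (anyDuplicated(channelMap))
        stop("channelMap roles must map to distinct planes")
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    ## a single page with a 3rd dimension carries its samples as planes
    if (length(pages) == 1L && length(dim(pages[[1L]])) == 3L) {
        arr <- pages[[1L]]
        pages <- lapply(seq_len(dim(arr)[3L]), function(s) {
            p <- arr[, , s]
            attributes(p) <- c(attributes(p),
                               attributes(arr)[c("x.resolution",
                                                 "resolution.unit")])
            p
        })
    }
    bad <- channelMap[channelMap > length(pages) | channelMap < 1L]
    if (length(bad))
        stop(sprintf("TIFF has %d plane(s); cannot map role(s): %s",
                     length(pages), paste(names(bad), collapse = ", ")))
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L))))
        stop("TIFF planes must be 2-D greyscale")
    ps <- .pixelSizeFromTiff(pages[[1L]])
    if (is.na(ps)) ps <- pixelSizeUm
    channels <- lapply(channelMap, function(i) {
        m <- pages[[i]]
        attributes(m) <- list(dim = dim(m))
        m * 65535
    })
    names(channels) <- names(channelMap)
    new("MultiChannelImage", channels = channels, pixelSize = ps,
        imageId = imageId)
}

.pixelSizeFromTiff <- function(page) {
    xres <- attr(page, "x.resolution")
    unit <- attr(page, "resolution.unit")
    if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NA_real_)
    ## resolution = pixels per unit; centimetres when the unit says so
    if (!is.null(unit) && identical(unit, "cm")) return(10000 / xres)
    if (!is.null(unit) && identical(unit, "inch")) return(25400 / xres)
    NA_real_
}

#' Write a multi-channel image as a multi-page 16-bit TIFF
#'
#' Channels are written in their stored order, quantised to the 16-bit
#' grey-level scale.  The baseline TIFF writer does not record resolution
#' tags, so the pixel size is not embedded: supply it again (e.g. via the
#' run configuration) when reading the file back.
#'
#' @param image a [MultiChannelImage-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeImage <- function(image, path) {
    stopifnot(is(image, "MultiChannelImage"))
    pages <- lapply(image@channels, function(m) {
        m <- pmin(pmax(round(m), 0), 65535) / 65535
        attributes(m) <- list(dim = dim(m))
        m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    invisible(path)
}

## mapping from QuPath measurement-export vocabulary to the native schema;
## exported as a default so users can adapt it to their QuPath version
.qupathCompartments <- c("Nucleus" = "nucleus", "Cytoplasm" = "cytoplasm",
                         "Cell" = "cell")
.qupathStatistics <- c("Mean" = "mean", "Median" = "median", "Min" = "min",
                       "Max" = "max", "Std.Dev." = "sd", "Std.dev." = "sd",
                       "mean" = "mean", "median" = "median", "min" = "min",
                       "max" = "max")

#' Read a per-cell measurement table
#'
#' Reads a delimited cell table in either the package's native CSV schema
#' (see [featureKey()]) or the QuPath measurement-export TSV dialect, whose
#' headers look like \code{"Nucleus: CY5 max"} and are translated to native
#' feature keys via a channel-role map and a fixed compartment/statistic
#' vocabulary.  Columns that match no known pattern are preserved untouched
#' as passthrough metadata.
#'
#' @param path delimited text file with a header row.
#' @param dialect \code{"native_csv"} or \code{"qupath_tsv"}.
#' @param channelMap named character vector raw-channel-name -> role used by
#'   the QuPath dialect, e.g. \code{c(DAPI = "dapi", FITC = "cytokeratin",
#'   TRITC = "fibronectin", CY5 = "marker")}.
#' @return data.frame in the native schema.  An empty file yields an empty
#'   table with a warning; a non-numeric value in a feature column is a
#'   row-level error reporting the offending row.
#' @export
readCellTable <- function(path, dialect = c("native_csv", "qupath_tsv"),
                          channelMap = c(DAPI = "dapi", FITC = "cytokeratin",
                                         TRITC = "fibronectin",
                                         CY5 = "marker")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "native_csv") "," else "\t"
    tab <- read.csv(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) {
        warning(sprintf("'%s' holds no cells", path), call. = FALSE)
        return(emptyCellTable())
    }
    if (dialect == "qupath_tsv")
        tab <- .translateQupath(tab, channelMap)
    if (!all(c("centroid_x_um", "centroid_y_um") %in% names(tab)))
        stop("cell table lacks centroid columns (centroid_x_um/centroid_y_um)")
    featureCols <- grep(
        "^(nucleus|cytoplasm|cell)\\.[^.]+\\.(mean|median|min|max|sd)$",
        names(tab), value = TRUE)
    numericCols <- unique(c("centroid_x_um", "centroid_y_um", featureCols,
        intersect(c("nucleus_area_um2", "signed_distance_um"), names(tab))))
    for (cn in numericCols) {
        v <- suppressWarnings(as.numeric(tab[[cn]]))
        bad <- which(is.na(v) & !is.na(tab[[cn]]) &
                     trimws(as.character(tab[[cn]])) != "")
        if (length(bad))
            stop(sprintf("non-numeric value in column '%s' at row %d",
                         cn, bad[1L]))
        tab[[cn]] <- v
    }
    if ("cell_id" %in% names(tab)) tab$cell_id <- as.integer(tab$cell_id)
    tab
}

.translateQupath <- function(tab, channelMap) {
    nm <- names(tab)
    direct <- c("Image" = "image_id", "Object ID" = "cell_id",
                "Centroid X µm" = "centroid_x_um",
                "Centroid Y µm" = "centroid_y_um",
                "Nucleus: Area µm^2" = "nucleus_area_um2")
    hit <- nm %in% names(direct)
    nm[hit] <- direct[nm[hit]]
    pat <- sprintf("^(%s): (.+) (%s)$",
                   paste(names(.qupathCompartments), collapse = "|"),
                   paste(unique(names(.qupathStatistics)), collapse = "|"))
    m <- regmatches(nm, regexec(pat, nm))
    for (i in seq_along(nm)) {
        if (length(m[[i]]) == 4L) {
            chan <- m[[i]][3L]
            role <- if (chan %in% names(channelMap)) channelMap[[chan]]
                    else chan
            nm[i] <- featureKey(.qupathCompartments[[m[[i]][2L]]], role,
                                .qupathStatistics[[m[[i]][4L]]])
        }
    }
    names(tab) <- nm
    tab
}

#' Write a cell table as native CSV
#'
#' Numeric columns are written with 17 significant digits so that
#' \code{readCellTable(writeCellTable(x))} round-trips every value
#' bit-exactly.
#'
#' @param cells cell table in the native schema.
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
writeCellTable <- function(cells, path) {
    out <- cells
    for (cn in names(out))
        if (is.double(out[[cn]]))
            out[[cn]] <- sprintf("%.17g", out[[cn]])
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

## ---- GeoJSON mask polygons ----------------------------------------------

## Trace the boundary of a logical mask as closed rings of pixel-edge
## vertices (integer pixel coordinates, converted to um on output).  Every
## unit edge between a mask pixel and a non-mask (or out-of-image) pixel
## appears in exactly one ring, so even-odd rasterisation of the rings
## reproduces the mask exactly.
.traceRings <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    segs <- list()
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
    idx <- which(pad, arr.ind = TRUE)
    r <- idx[, 1L] - 1L; c <- idx[, 2L] - 1L   # back to 1-based mask coords
    up <- !pad[cbind(idx[, 1L] - 1L, idx[, 2L])]
    dn <- !pad[cbind(idx[, 1L] + 1L, idx[, 2L])]
    lf <- !pad[cbind(idx[, 1L], idx[, 2L] - 1L)]
    rt <- !pad[cbind(idx[, 1L], idx[, 2L] + 1L)]
    ## vertices keyed as x * (nr+1) + y with x in 0..nc, y in 0..nr
    key <- function(x, y) x * (nr + 1L) + y
    seg <- rbind(
        cbind(key(c[up] - 1L, r[up] - 1L), key(c[up], r[up] - 1L)),
        cbind(key(c[dn] - 1L, r[dn]), key(c[dn], r[dn])),
        cbind(key(c[lf] - 1L, r[lf] - 1L), key(c[lf] - 1L, r[lf])),
        cbind(key(c[rt], r[rt] - 1L), key(c[rt], r[rt])))
    if (nrow(seg) == 0L) return(list())
    ## chain undirected unit segments into closed loops
    nseg <- nrow(seg)
    used <- logical(nseg)
    inc <- split(rep(seq_len(nseg), 2L), c(seg[, 1L], seg[, 2L]))
    rings <- list()
    for (s0 in seq_len(nseg)) {
        if (used[s0]) next
        used[s0] <- TRUE
        start <- seg[s0, 1L]
        cur <- seg[s0, 2L]
        ring <- c(start, cur)
        while (cur != start) {
            cand <- inc[[as.character(cur)]]
            nxt <- cand[!used[cand]][1L]
            used[nxt] <- TRUE
            cur <- if (seg[nxt, 1L] == cur) seg[nxt, 2L] else seg[nxt, 1L]
            ring <- c(ring, cur)
        }
        x <- ring %/% (nr + 1L)
        y <- ring %% (nr + 1L)
        rings[[length(rings) + 1L]] <- cbind(x = x, y = y)
    }
    rings
}

.ringArea <- function(ring) {
    x <- ring[, 1L]; y <- ring[, 2L]
    n <- nrow(ring)
    sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

## even-odd point-in-rings test for all pixel centres; rings in pixel units
.rasterizeRings <- function(rings, dim) {
    nr <- dim[1L]; nc <- dim[2L]
    px <- rep(seq_len(nc) - 0.5, each = nr)
    py <- rep(seq_len(nr) - 0.5, times = nc)
    crossings <- integer(nr * nc)
    for (ring in rings) {
        x <- ring[, 1L]
        y <- ring[, 2L]
        n <- nrow(ring)
        for (i in seq_len(n - 1L)) {
            y1 <- y[i]; y2 <- y[i + 1L]
            if (y1 == y2) next           # horizontal edges never cross
            x1 <- x[i]; x2 <- x[i + 1L]
            span <- (y1 > py) != (y2 > py)
            xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
            crossings <- crossings + (span & px < xi)
        }
    }
    matrix(crossings %% 2L == 1L, nr, nc)
}

#' Export a binary mask as GeoJSON polygons
#'
#' Writes the connected components of a binary mask as a GeoJSON
#' FeatureCollection (one Feature per component; holes are interior rings).
#' Vertices lie on pixel edges in micrometre coordinates (origin top-left),
#' so re-rasterising the polygons with [readMaskAsLabels()] reproduces the
#' source mask exactly.
#'
#' @param mask logical matrix or [StromaMask-class].
#' @param pixelSize micrometres per pixel (taken from the
#'   [StromaMask-class] when given).
#' @param path output file.
#' @return invisibly, the path.  An empty mask yields a valid file with
#'   zero features.
#' @export
writeMaskPolygons <- function(mask, pixelSize = NULL, path) {
    if (is(mask, "StromaMask")) {
        pixelSize <- pixelSize(mask)
        mask <- maskMatrix(mask)
    }
    stopifnot(is.matrix(mask))
    .assertScalarNumber(pixelSize, "pixelSize", positive = TRUE)
    mask <- mask > 0
    comp <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                   nrow(mask), ncol(mask))
    features <- list()
    for (k in seq_len(max(comp, 0L))) {
        rings <- .traceRings(comp == k)
        ## outer ring = largest absolute area; the rest are holes
        areas <- vapply(rings, .ringArea, numeric(1L))
        ord <- order(-abs(areas))
        rings <- rings[ord]
        coords <- lapply(seq_along(rings), function(i) {
            ring <- rings[[i]]
            a <- .ringArea(ring)
            ## GeoJSON: exterior counter-clockwise, holes clockwise
            wantCCW <- i == 1L
            if ((a > 0) != wantCCW) ring <- ring[rev(seq_len(nrow(ring))), ,
                                                 drop = FALSE]
            lapply(seq_len(nrow(ring)), function(j)
                c(ring[j, 1L], ring[j, 2L]) * pixelSize)
        })
        features[[length(features) + 1L]] <- list(
            type = "Feature",
            properties = list(object_id = k,
                              area_um2 = abs(.ringArea(rings[[1L]])) *
                                  pixelSize^2),
            geometry = list(type = "Polygon", coordinates = coords))
    }
    gj <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read GeoJSON polygons
#'
#' \code{readMaskPolygons()} returns, per feature, the list of rings as
#' two-column matrices in micrometre coordinates.  \code{readMaskAsLabels()}
#' rasterises the features onto a pixel grid (even-odd rule at pixel
#' centres) and returns an integer label matrix.
#'
#' @param path GeoJSON file written by [writeMaskPolygons()] (or compatible).
#' @param dim image dimension \code{c(rows, cols)}.
#' @param pixelSize micrometres per pixel.
#' @return see above.
#' @export
readMaskPolygons <- function(path) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection"))
        stop("not a GeoJSON FeatureCollection")
    lapply(gj$features, function(f) {
        lapply(f$geometry$coordinates, function(ring)
            do.call(rbind, lapply(ring, function(v)
                c(x = v[[1L]], y = v[[2L]]))))
    })
}

#' @rdname readMaskPolygons
#' @export
readMaskAsLabels <- function(path, dim, pixelSize) {
    feats <- readMaskPolygons(path)
    lab <- matrix(0L, dim[1L], dim[2L])
    for (k in seq_along(feats)) {
        rings <- lapply(feats[[k]], function(r) r / pixelSize)
        hit <- .rasterizeRings(rings, dim)
        lab[hit] <- k
    }
    lab
}

#' Read a YAML run configuration
#'
#' Loads the run configuration consumed by [runPipeline()] and the
#' command-line driver, fills unset keys with the documented defaults and
#' validates the schema.
#'
#' @param path YAML file; \code{NULL} returns the defaults.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path = NULL) {
    cfg <- defaultRunConfig()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        unknown <- setdiff(names(user), names(cfg))
        if (length(unknown))
            stop(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
        cfg[names(user)] <- user
    }
    for (key in c("pixel_size_um", "sigma", "stroma_threshold", "bin_width_um",
                  "n_boot", "seed", "n_images", "n_cells", "top_fraction"))
        .assertScalarNumber(cfg[[key]], key)
    if (cfg$bin_width_um <= 0) stop("bin_width_um must be > 0")
    if (cfg$n_images < 1) stop("n_images must be >= 1")
    cfg
}

#' @rdname readRunConfig
#' @export
defaultRunConfig <- function() list(
    pixel_size_um = 1.286,
    image_size_px = 512L,
    n_images = 3L,
    n_cells = 300L,
    sigma = 4,
    stroma_threshold = 12000,
    bin_width_um = 10,
    range_um = c(-100, 300),
    marker_feature = "cell.marker.max",
    top_fraction = 0.10,
    ker_threshold = 8000,
    reference_image = "phantom_1",
    n_boot = 200L,
    grid_sigmas = c(2, 4, 8),
    grid_thresholds = c(9000, 12000, 15000),
    batch_scales = c(1.0, 1.5, 0.8),
    seed = 1L)
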