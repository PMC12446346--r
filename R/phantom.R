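#' Build a phantom simulation configuration
#'
#' The phantom emulates the structure of a multiplexed immunofluorescence
#' image of a stroma-rich tumor at a reduced scale: a known stromal
#' geometry, a few hundred non-touching nuclei, a cytokeratin-high cancer
#' subset, and a marker whose per-cell intensity is log-normal with a
#' log-scale location shifted by a distance-effect term \eqn{g(d)} evaluated
#' at the cell's true signed distance to the stromal border.  Per-image
#' staining variability enters as a purely multiplicative intensity scale
#' \eqn{c}; in that regime the percentile-mapped threshold has the exact
#' closed form \eqn{t_j = c\,t_i}, which is what makes the phantom usable
#' for parameter-recovery tests.
#'
#' Defaults: 512 x 512 px at 1.286 um/px (a 4x coarser grid than the 0.3215
#' um/px of typical 20x whole-slide scans, so ~300 cells and a 5 um
#' expansion stay resolvable), a vertical stromal band, log-normal marker
#' with location \code{log(5000)} and scale 0.5 on the 16-bit grey scale,
#' and a distance effect peaked at the border,
#' \code{g(d) = exp(-abs(d)/50)}.
#'
#' @param imageSize image size in pixels, length 1 or 2 (rows, cols).
#' @param pixelSize micrometres per pixel.
#' @param stromaGeometry \code{"band"} (vertical band), \code{"annulus"} or
#'   \code{"blobs"} (thresholded smoothed noise).
#' @param geometryParams named list; for \code{band}: \code{x0}, \code{x1}
#'   (um); for \code{annulus}: \code{cx}, \code{cy}, \code{r0}, \code{r1}
#'   (um); for \code{blobs}: \code{smooth} (px), \code{fill} (target stromal
#'   fraction).  Unset values default to a band/annulus covering roughly a
#'   third of the image.
#' @param nCells number of cells to place.
#' @param nucleusRadiusMean,nucleusRadiusSd nuclear radius in um.
#' @param markerMu,markerSigma baseline log-scale location and scale.
#' @param distanceEffect function of the true signed distance (um) added to
#'   the log-scale location.
#' @param batchScale multiplicative intensity scale of this image.
#' @param noiseSd additive Gaussian noise sd on the DAPI and fibronectin
#'   channels, in grey levels.
#' @param cancerFraction fraction of cells in the cytokeratin-high subset.
#' @param markerThreshold reference-scale marker threshold defining
#'   ground-truth positivity (defaults to the 90th percentile of the
#'   baseline log-normal, i.e. a top-10\% rule at g = 0).
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return A [PhantomConfig-class].
#' @export
#' @examples
#' cfg <- phantomConfig(nCells = 50L, seed = 7L)
#' cfg
phantomConfig <- function(imageSize = c(512L, 512L), pixelSize = 1.286,
                          stromaGeometry = c("band", "annulus", "blobs"),
                          geometryParams = list(), nCells = 300L,
                          nucleusRadiusMean = 4, nucleusRadiusSd = 0.5,
                          markerMu = log(5000), markerSigma = 0.5,
                          distanceEffect = function(d) exp(-abs(d) / 50),
                          batchScale = 1, noiseSd = 600,
                          cancerFraction = 0.7, markerThreshold = NULL,
                          seed = 1L) {
    stromaGeometry <- match.arg(stromaGeometry)
    if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
    if (is.null(markerThreshold))
        markerThreshold <- exp(markerMu + 1.2815516 * markerSigma)
    new("PhantomConfig", imageSize = as.integer(imageSize),
        pixelSize = pixelSize, stromaGeometry = stromaGeometry,
        geometryParams = geometryParams, nCells = as.integer(nCells),
        nucleusRadiusMean = nucleusRadiusMean,
        nucleusRadiusSd = nucleusRadiusSd, markerMu = markerMu,
        markerSigma = markerSigma, distanceEffect = distanceEffect,
        batchScale = batchScale, noiseSd = noiseSd,
        cancerFraction = cancerFraction, markerThreshold = markerThreshold,
        seed = as.integer(seed))
}

## stroma truth mask + analytic signed distance at arbitrary um points
.phantomStroma <- function(config) {
    nr <- config@imageSize[1L]; nc <- config@imageSize[2L]
    ps <- config@pixelSize
    gp <- config@geometryParams
    xs <- (seq_len(nc) - 0.5) * ps
    ys <- (seq_len(nr) - 0.5) * ps
    switch(config@stromaGeometry,
        band = {
            x0 <- gp$x0 %||% (nc * ps / 3)
            x1 <- gp$x1 %||% (2 * nc * ps / 3)
            mask <- matrix(rep(xs >= x0 & xs < x1, each = nr), nr, nc)
            dist <- function(x, y)
                ifelse(x >= x0 & x < x1, -pmin(x - x0, x1 - x),
                       pmax(x0 - x, x - x1))
            list(mask = mask, distance = dist)
        },
        annulus = {
            cx <- gp$cx %||% (nc * ps / 2)
            cy <- gp$cy %||% (nr * ps / 2)
            r0 <- gp$r0 %||% (nc * ps / 6)
            r1 <- gp$r1 %||% (nc * ps / 3)
            rr <- sqrt(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2))
            mask <- rr >= r0 & rr < r1
            dist <- function(x, y) {
                r <- sqrt((x - cx)^2 + (y - cy)^2)
                ifelse(r >= r0 & r < r1, -pmin(r - r0, r1 - r),
                       pmax(r0 - r, r - r1))
            }
            list(mask = mask, distance = dist)
        },
        blobs = {
            smooth <- gp$smooth %||% 12
            fill <- gp$fill %||% (1 / 3)
            noise <- matrix(rnorm(nr * nc), nr, nc)
            sm <- .im2mat(EBImage::gblur(noise, sigma = smooth))
            mask <- sm > quantile(sm, 1 - fill, names = FALSE)
            ## no closed form: signed distance from the rasterised mask
            dm <- distanceMatrix(signedDistanceMap(mask, config@pixelSize))
            dist <- function(x, y) {
                col <- pmin(pmax(floor(x / ps) + 1L, 1L), nc)
                row <- pmin(pmax(floor(y / ps) + 1L, 1L), nr)
                dm[cbind(row, col)]
            }
            list(mask = mask, distance = dist)
        })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## place non-overlapping cells; bounded rejection sampling
.placeCells <- function(config) {
    n <- config@nCells
    ps <- config@pixelSize
    nr <- config@imageSize[1L]; nc <- config@imageSize[2L]
    radii <- pmax(rnorm(n, config@nucleusRadiusMean, config@nucleusRadiusSd),
                  ps)
    margin <- max(radii) + ps
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    maxAttempts <- 1000L * max(n, 1L)
    while (placed < n) {
        if (attempts >= maxAttempts)
            stop(sprintf(
                "could not place %d non-overlapping cells after %d attempts; lower the cell density",
                n, maxAttempts))
        attempts <- attempts + 1L
        x <- runif(1L, margin, nc * ps - margin)
        y <- runif(1L, margin, nr * ps - margin)
        if (placed > 0L) {
            i <- seq_len(placed)
            minSep <- radii[i] + radii[placed + 1L] + 3 * ps
            if (any((xs[i] - x)^2 + (ys[i] - y)^2 < minSep^2)) next
        }
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y
    }
    data.frame(cell_id = seq_len(n), centroid_x_um = xs, centroid_y_um = ys,
               radius_um = radii)
}

.paintDisks <- function(mat, xs, ys, radiiUm, values, ps) {
    nr <- nrow(mat); nc <- ncol(mat)
    for (i in seq_along(xs)) {
        r <- radiiUm[i] / ps
        cx <- xs[i] / ps; cy <- ys[i] / ps
        c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r) + 1L)
        r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r) + 1L)
        cols <- c0:c1; rows <- r0:r1
        d2 <- outer((rows - 0.5 - cy)^2, (cols - 0.5 - cx)^2, "+")
        sub <- mat[rows, cols, drop = FALSE]
        sub[d2 <= r^2] <- values[i]
        mat[rows, cols] <- sub
    }
    mat
}

#' Generate a phantom multi-channel image with ground truth
#'
#' Simulates one four-channel image: DAPI (nuclear disks plus noise),
#' pan-cytokeratin (high over the cancer subset's cell disks),
#' fibronectin (smoothed stromal mask times a fixed intensity plus noise)
#' and the marker channel, where each cell's disk is painted with its
#' log-normal intensity draw \eqn{c \cdot \exp(N(\mu + g(d), \sigma))}.
#' All randomness is governed by the config seed, so a rerun is
#' byte-identical.
#'
#' @param config a [PhantomConfig-class].
#' @param allowEmpty permit \code{nCells = 0} (an empty image); otherwise an
#'   error.
#' @param imageId identifier of the generated image; defaults to
#'   \code{"phantom_<seed>"}.
#' @return list with \code{image} (a [MultiChannelImage-class], channels
#'   \code{dapi}, \code{cytokeratin}, \code{fibronectin}, \code{marker}) and
#'   \code{truth}: \code{stromaMask} (logical matrix), \code{cells}
#'   (data.frame with true centroid, radius, signed distance, marker draw,
#'   cancer membership and marker positivity), \code{batchScale},
#'   \code{markerThreshold} (already scaled by \code{batchScale}) and
#'   \code{fibronectinIntensity}.
#' @export
#' @examples
#' ph <- generatePhantomImage(phantomConfig(nCells = 40L, seed = 7L))
#' ph$image
#' head(ph$truth$cells)
generatePhantomImage <- function(config, allowEmpty = FALSE,
                                 imageId = sprintf("phantom_%d",
                                                   config@seed)) {
    stopifnot(is(config, "PhantomConfig"))
    if (config@nCells == 0L && !allowEmpty)
        stop("nCells = 0; pass allowEmpty = TRUE for an intentionally empty image")
    nr <- config@imageSize[1L]; nc <- config@imageSize[2L]
    ps <- config@pixelSize
    fnIntensity <- 20000
    withSeed(config@seed, {
        stroma <- .phantomStroma(config)
        cells <- if (config@nCells > 0L) .placeCells(config)
                 else data.frame(cell_id = integer(0),
                                 centroid_x_um = numeric(0),
                                 centroid_y_um = numeric(0),
                                 radius_um = numeric(0))
        d <- stroma$distance(cells$centroid_x_um, cells$centroid_y_um)
        cells$distance_um <- as.numeric(d)
        n <- nrow(cells)
        g <- config@distanceEffect(cells$distance_um)
        cells$marker_value <- config@batchScale *
            rlnorm(n, config@markerMu + g, config@markerSigma)
        cells$cancer <- runif(n) < config@cancerFraction
        scaledT <- config@batchScale * config@markerThreshold
        cells$marker_positive <- cells$marker_value > scaledT

        dapi <- matrix(rnorm(nr * nc, 1000, config@noiseSd), nr, nc)
        dapi <- .paintDisks(dapi, cells$centroid_x_um, cells$centroid_y_um,
                            cells$radius_um, rep(30000, n), ps)
        ker <- matrix(2000, nr, nc)
        cancer <- which(cells$cancer)
        ker <- .paintDisks(ker, cells$centroid_x_um[cancer],
                           cells$centroid_y_um[cancer],
                           cells$radius_um[cancer] + 5,
                           rep(15000, length(cancer)), ps)
        fn <- .im2mat(EBImage::gblur(stroma$mask * fnIntensity, sigma = 2)) +
            matrix(rnorm(nr * nc, 0, config@noiseSd), nr, nc)
        marker <- matrix(0, nr, nc)
        marker <- .paintDisks(marker, cells$centroid_x_um,
                              cells$centroid_y_um, cells$radius_um,
                              cells$marker_value, ps)
        channels <- lapply(list(dapi = dapi, cytokeratin = ker,
                                fibronectin = fn, marker = marker),
                           function(m) pmin(pmax(round(m), 0), 65535))
        img <- new("MultiChannelImage", channels = channels, pixelSize = ps,
                   imageId = imageId)
        list(image = img,
             truth = list(stromaMask = stroma$mask, cells = cells,
                          batchScale = config@batchScale,
                          markerThreshold = scaledT,
                          fibronectinIntensity = fnIntensity))
    })
}

#' Generate a batch of per-image cell tables with multiplicative shifts
#'
#' Draws, for each of \code{nImages} images, \code{config@nCells} cells
#' with uniformly distributed signed distances and marker values
#' \eqn{c_k \exp(N(\mu + g(d), \sigma))}: image k's values are those of the
#' reference generator multiplied by the batch scale \eqn{c_k}.  The
#' ground-truth threshold of image k is therefore exactly
#' \eqn{c_k \cdot t_{ref}} — the quantity percentile mapping must recover.
#'
#' @param config a [PhantomConfig-class] (its \code{nCells}, marker model
#'   and seed are used).
#' @param nImages number of images in the batch (>= 1).
#' @param scales numeric vector of per-image multiplicative factors
#'   \eqn{c_k}; recycled defaults to 1.
#' @param distanceRange range (um) the true signed distances are drawn from.
#' @return list with \code{tables} (named list of native-schema cell
#'   tables, image ids \code{phantom_1..K}) and \code{truth}: the
#'   \code{scales}, the per-image \code{thresholds} \eqn{c_k t_{ref}} and
#'   the generator parameters.
#' @export
#' @examples
#' batch <- generateCellTableBatch(phantomConfig(nCells = 500L, seed = 3L),
#'                                 nImages = 2, scales = c(1, 1.5))
#' sapply(batch$tables, function(tab) median(tab$cell.marker.max))
generateCellTableBatch <- function(config, nImages, scales = 1,
                                   distanceRange = c(-100, 300)) {
    stopifnot(is(config, "PhantomConfig"))
    if (nImages < 1L) stop("nImages must be >= 1")
    scales <- rep_len(scales, nImages)
    if (any(scales <= 0)) stop("scales must be > 0")
    n <- config@nCells
    key <- featureKey("cell", "marker", "max")
    tables <- vector("list", nImages)
    names(tables) <- sprintf("phantom_%d", seq_len(nImages))
    for (k in seq_len(nImages)) {
        tables[[k]] <- withSeed(childSeed(config@seed, k), {
            d <- runif(n, distanceRange[1L], distanceRange[2L])
            g <- config@distanceEffect(d)
            val <- scales[k] * rlnorm(n, config@markerMu + g,
                                      config@markerSigma)
            tab <- data.frame(
                image_id = names(tables)[k],
                cell_id = seq_len(n),
                centroid_x_um = runif(n, 0, config@imageSize[2L] *
                                      config@pixelSize),
                centroid_y_um = runif(n, 0, config@imageSize[1L] *
                                      config@pixelSize),
                nucleus_area_um2 = pi * pmax(
                    rnorm(n, config@nucleusRadiusMean,
                          config@nucleusRadiusSd), 0.5)^2,
                signed_distance_um = d,
                stringsAsFactors = FALSE)
            tab[[key]] <- val
            tab
        })
    }
    list(tables = tables,
         truth = list(scales = scales,
                      thresholds = scales * config@markerThreshold,
                      markerMu = config@markerMu,
                      markerSigma = config@markerSigma))
}
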