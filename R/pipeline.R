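#' Run the full spatial-analysis chain on a phantom batch
#'
#' End-to-end driver mirroring the analysis workflow: simulate a phantom
#' image batch, segment nuclei and expand cells, extract per-compartment
#' features and filter by nuclear area, model the stromal mask and assign
#' signed border distances, propagate the reference marker threshold across
#' the batch by percentile mapping, classify cells (marker, cytokeratin,
#' composite), build distance-binned intensity profiles for the positive
#' and negative populations, and run the stroma-parameter sensitivity grid.
#' Every stage's seed is derived deterministically from the single
#' configuration seed, so two runs with the same configuration produce
#' byte-identical outputs.
#'
#' Outputs written to \code{outDir}: \code{config.yaml} (the resolved
#' configuration), \code{cells.csv} (all cells with distances and labels),
#' \code{thresholds.json}, \code{stroma_<image>.geojson},
#' \code{profile_positive.csv}, \code{profile_negative.csv},
#' \code{profile_difference.csv}, \code{sensitivity.csv},
#' \code{sensitivity_summary.json} and \code{log.txt}.
#'
#' @param config configuration list from [readRunConfig()] /
#'   [defaultRunConfig()].
#' @param outDir output directory (created if absent).
#' @param writeImages also write the simulated images as multi-page TIFFs.
#' @return invisibly, a list with the in-memory results (\code{cells},
#'   \code{thresholds}, \code{profiles}, \code{sensitivity}).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir,
                        writeImages = FALSE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logLines <- character(0)
    note <- function(fmt, ...) {
        line <- sprintf(fmt, ...)
        logLines <<- c(logLines, line)
        message(line)
    }
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))

    ## ---- simulate -------------------------------------------------------
    nImages <- config$n_images
    scales <- rep_len(config$batch_scales, nImages)
    ids <- sprintf("phantom_%d", seq_len(nImages))
    images <- list(); truths <- list()
    for (k in seq_len(nImages)) {
        cfg <- phantomConfig(imageSize = config$image_size_px,
                             pixelSize = config$pixel_size_um,
                             nCells = config$n_cells,
                             batchScale = scales[k],
                             seed = childSeed(config$seed, k))
        ph <- generatePhantomImage(cfg, imageId = ids[k])
        images[[ids[k]]] <- ph$image
        truths[[ids[k]]] <- ph$truth
        if (writeImages)
            writeImage(ph$image, file.path(outDir, paste0(ids[k], ".tif")))
    }
    note("simulated %d phantom image(s), scales: %s", nImages,
         paste(scales, collapse = ", "))

    ## ---- segment + features ---------------------------------------------
    tables <- list()
    for (id in ids) {
        img <- images[[id]]
        nuc <- segmentNuclei(getChannel(img, "dapi"))
        masks <- expandCells(nuc, radiusUm = 5, pixelSize = pixelSize(img))
        tab <- extractFeatures(img, nuc, masks)
        tab <- suppressMessages(filterByNuclearArea(tab))
        tables[[id]] <- tab
        note("%s: %d cells after nuclear-area filter", id, nrow(tab))
    }

    ## ---- stroma + distances ---------------------------------------------
    for (id in ids) {
        mask <- buildStromaMask(images[[id]], sigma = config$sigma,
                                threshold = config$stroma_threshold)
        writeMaskPolygons(mask,
                          path = file.path(outDir,
                                           sprintf("stroma_%s.geojson", id)))
        dm <- signedDistanceMap(mask)
        tables[[id]] <- assignCellDistances(tables[[id]], dm)
    }
    note("stromal masks built (sigma = %g px, threshold = %g)",
         config$sigma, config$stroma_threshold)

    ## ---- calibrate -------------------------------------------------------
    refTab <- tables[[config$reference_image]]
    tRef <- percentileThreshold(refTab[[config$marker_feature]],
                                config$top_fraction)
    ths <- propagateThresholds(tables, config$marker_feature,
                               config$reference_image, tRef)
    writeFitReport(ths, file.path(outDir, "thresholds.json"))
    note("reference threshold %.4g propagated to %d image(s)", tRef,
         length(thresholds(ths)))

    ## ---- classify --------------------------------------------------------
    kerKey <- featureKey("cell", "cytokeratin", "mean")
    for (id in ids) {
        tables[[id]] <- applyThresholdClassifier(
            tables[[id]], config$marker_feature,
            thresholds(ths)[[id]], "marker")
        tables[[id]] <- applyThresholdClassifier(
            tables[[id]], kerKey, config$ker_threshold %||% 8000,
            "cytokeratin")
        tables[[id]] <- compositePositive(tables[[id]])
    }
    cells <- do.call(rbind, tables)
    rownames(cells) <- NULL
    writeCellTable(cells, file.path(outDir, "cells.csv"))
    note("classified %d cells; %d composite positive", nrow(cells),
         sum(cells$label.marker_cancer == "positive", na.rm = TRUE))

    ## ---- profiles --------------------------------------------------------
    pos <- cells[!is.na(cells$label.marker_cancer) &
                 cells$label.marker_cancer == "positive", ]
    neg <- cells[!is.na(cells$label.marker_cancer) &
                 cells$label.marker_cancer == "negative", ]
    profPos <- spatialProfile(pos, config$marker_feature,
                              binWidthUm = config$bin_width_um,
                              rangeUm = config$range_um,
                              nBoot = config$n_boot,
                              seed = childSeed(config$seed, 101L),
                              population = "marker-positive cancer cells")
    profNeg <- spatialProfile(neg, config$marker_feature,
                              binWidthUm = config$bin_width_um,
                              rangeUm = config$range_um,
                              nBoot = config$n_boot,
                              seed = childSeed(config$seed, 102L),
                              population = "marker-negative cells")
    writeProfile(profPos, file.path(outDir, "profile_positive.csv"))
    writeProfile(profNeg, file.path(outDir, "profile_negative.csv"))
    pd <- profileDifference(profPos, profNeg)
    for (cn in c("difference", "sem"))
        pd[[cn]] <- sprintf("%.17g", pd[[cn]])
    write.csv(pd, file.path(outDir, "profile_difference.csv"),
              row.names = FALSE)
    note("profiles written (%d bins of %g um)",
         length(binEdges(profPos)) - 1L, config$bin_width_um)

    ## ---- sensitivity -----------------------------------------------------
    sens <- runSensitivityGrid(images, tables,
                               sigmas = config$grid_sigmas,
                               thresholds = config$grid_thresholds,
                               feature = config$marker_feature,
                               nBoot = config$n_boot,
                               seed = childSeed(config$seed, 103L))
    longOut <- sens$correlations
    longOut$r <- sprintf("%.17g", longOut$r)
    write.csv(longOut, file.path(outDir, "sensitivity.csv"),
              row.names = FALSE)
    jsonlite::write_json(
        list(summary = sens$summary,
             pooled_wilcoxon = sens$wilcoxon, n_pairs = sens$nPairs),
        file.path(outDir, "sensitivity_summary.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    note("sensitivity grid: %d x %d points, pooled Wilcoxon p = %s",
         length(config$grid_sigmas), length(config$grid_thresholds),
         if (is.null(sens$wilcoxon)) "NA"
         else sprintf("%.3g", sens$wilcoxon$p.value))

    writeLines(logLines, file.path(outDir, "log.txt"))
    invisible(list(cells = cells, thresholds = ths,
                   profiles = list(positive = profPos, negative = profNeg,
                                   difference = pd),
                   sensitivity = sens, truths = truths))
}
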