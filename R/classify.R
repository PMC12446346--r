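#' Threshold-based cell classification
#'
#' Labels every cell positive or negative by comparing one feature column to
#' a threshold: positive iff \code{feature > threshold} (strict, so ties are
#' negative).  The label is stored in the column \code{label.<labelName>} as
#' \code{"positive"} / \code{"negative"}; cells with a missing feature value
#' are left \code{NA} and flagged.
#'
#' @param cells cell table in the native schema.
#' @param feature feature column, e.g. \code{"cell.marker.max"} (whole-cell
#'   maximum suits cytoplasmic-plus-nuclear markers,
#'   \code{"nucleus.marker.max"} strictly nuclear ones).
#' @param threshold numeric threshold.
#' @param labelName name under which the label is stored.
#' @return the cell table with the label column added.
#' @export
#' @examples
#' tab <- data.frame(cell.marker.max = c(1, 5, 9))
#' applyThresholdClassifier(tab, "cell.marker.max", 5)$label.marker
applyThresholdClassifier <- function(cells, feature, threshold,
                                     labelName = "marker") {
    if (!feature %in% names(cells))
        stop(sprintf("feature '%s' not present in the cell table", feature))
    .assertScalarNumber(threshold, "threshold")
    v <- cells[[feature]]
    lab <- ifelse(v > threshold, "positive", "negative")
    miss <- !is.finite(v)
    lab[miss] <- NA_character_
    if (any(miss))
        warning(sprintf("%d cell(s) lack feature '%s' and were left unlabeled",
                        sum(miss), feature), call. = FALSE)
    cells[[paste0("label.", labelName)]] <- lab
    cells
}

#' Composite marker-positive cancer cells
#'
#' Restricts marker positivity to cancer cells: composite positive iff
#' marker-positive AND cytokeratin-positive.  This is the standard cancer-
#' cell restriction — e.g. "Ki67+" meaning Ki67-positive and
#' pan-cytokeratin-positive.
#'
#' @param cells cell table carrying both label columns.
#' @param markerLabel,cytokeratinLabel label names (without the
#'   \code{label.} prefix).
#' @param labelName name of the composite label (default
#'   \code{"<marker>_cancer"}).
#' @return the cell table with the composite label column added.
#' @export
compositePositive <- function(cells, markerLabel = "marker",
                              cytokeratinLabel = "cytokeratin",
                              labelName = paste0(markerLabel, "_cancer")) {
    mcol <- paste0("label.", markerLabel)
    kcol <- paste0("label.", cytokeratinLabel)
    if (!all(c(mcol, kcol) %in% names(cells)))
        stop("both labels must be assigned before building the composite")
    pos <- cells[[mcol]] == "positive" & cells[[kcol]] == "positive"
    cells[[paste0("label.", labelName)]] <-
        ifelse(is.na(pos), NA_character_,
               ifelse(pos, "positive", "negative"))
    cells
}

#' Confusion matrix and agreement between two labelings
#'
#' Cross-tabulates two labelings of the same cells and reports the agreement
#' percentage, 100 x trace / total.  Rows index labeling A, columns
#' labeling B.
#'
#' @param labelsA,labelsB character vectors of equal length (class names),
#'   or names of label columns when \code{cells} is given.
#' @param cells optional cell table to take the label columns from.
#' @return A [ConfusionResult-class].
#' @export
#' @examples
#' a <- rep(c("positive", "negative"), c(60, 40))
#' b <- rep(c("positive", "negative", "positive"), c(50, 45, 5))
#' agreement(confusionMatrix(a, b))
confusionMatrix <- function(labelsA, labelsB, cells = NULL) {
    if (!is.null(cells)) {
        labelsA <- cells[[paste0("label.", labelsA)]]
        labelsB <- cells[[paste0("label.", labelsB)]]
    }
    if (length(labelsA) != length(labelsB))
        stop("labelings must cover the same cells (length mismatch)")
    keep <- !is.na(labelsA) & !is.na(labelsB)
    labelsA <- labelsA[keep]; labelsB <- labelsB[keep]
    if (length(labelsA) == 0L) stop("no jointly labeled cells")
    classes <- sort(unique(c(labelsA, labelsB)))
    counts <- table(factor(labelsA, classes), factor(labelsB, classes))
    counts <- matrix(as.integer(counts), length(classes), length(classes),
                     dimnames = list(A = classes, B = classes))
    new("ConfusionResult", classes = classes, counts = counts,
        agreement = 100 * sum(diag(counts)) / sum(counts))
}

#' Import externally produced cell labels
#'
#' Merges class labels predicted outside the package (e.g. by a trained
#' classifier in an interactive image-analysis platform) into the cell
#' table, keyed by \code{cell_id}.  Duplicated ids in the file are an
#' error; cells without a matching row stay unlabeled and are reported.
#'
#' @param cells cell table.
#' @param path CSV with columns \code{cell_id} and \code{class}.
#' @param labelName name under which the imported label is stored.
#' @return the cell table with the label column added; the number of
#'   unmatched cells is reported via \code{message()}.
#' @export
importExternalLabels <- function(cells, path, labelName = "external") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "class") %in% names(tab)))
        stop("label file must have 'cell_id' and 'class' columns")
    if (anyDuplicated(tab$cell_id))
        stop(sprintf("duplicated cell_id in label file: %s",
                     tab$cell_id[duplicated(tab$cell_id)][1L]))
    m <- match(cells$cell_id, tab$cell_id)
    cells[[paste0("label.", labelName)]] <- tab$class[m]
    if (anyNA(m))
        message(sprintf("%d cell(s) had no label in '%s'", sum(is.na(m)),
                        path))
    cells
}

#' Export a confusion matrix
#'
#' @param result a [ConfusionResult-class].
#' @param path output file; \code{.csv} writes the count matrix,
#'   \code{.json} a full report with the agreement percentage.
#' @return invisibly, the path.
#' @export
writeConfusion <- function(result, path) {
    stopifnot(is(result, "ConfusionResult"))
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::write_json(list(
            classes = result@classes,
            counts = result@counts,
            agreement_pct = result@agreement), path, auto_unbox = TRUE,
            digits = NA, matrix = "rowmajor")
    } else {
        write.csv(as.data.frame(result@counts), path)
    }
    invisible(path)
}
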