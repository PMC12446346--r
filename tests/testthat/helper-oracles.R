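## Brute-force oracles used across tests.  These deliberately use the
## slowest, most literal computation available so they stay independent of
## the implementation they check.

## O(N^2) signed Euclidean distance: per pixel, minimum distance over all
## opposite-phase pixel centres, negative inside the mask.
bruteSignedDistance <- function(mask, pixelSize = 1) {
    nr <- nrow(mask); nc <- ncol(mask)
    xy <- arrayInd(seq_len(nr * nc), c(nr, nc))
    rows <- xy[, 1L]; cols <- xy[, 2L]
    inIdx <- which(mask); outIdx <- which(!mask)
    out <- numeric(nr * nc)
    for (p in seq_len(nr * nc)) {
        if (mask[p]) {
            out[p] <- -sqrt(min((rows[outIdx] - rows[p])^2 +
                                (cols[outIdx] - cols[p])^2))
        } else {
            out[p] <- sqrt(min((rows[inIdx] - rows[p])^2 +
                               (cols[inIdx] - cols[p])^2))
        }
    }
    matrix(out * pixelSize, nr, nc)
}

## brute-force nearest-nucleus expansion: per pixel, scan every nucleus
## pixel of every label; assign to the closest label within radius (ties to
## the lower label)
bruteExpand <- function(labelMask, radiusPx) {
    nr <- nrow(labelMask); nc <- ncol(labelMask)
    labs <- sort(unique(labelMask[labelMask > 0L]))
    out <- matrix(0L, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (labelMask[r, c] > 0L) { out[r, c] <- labelMask[r, c]; next }
        best <- Inf; bestLab <- 0L
        for (k in labs) {
            idx <- which(labelMask == k, arr.ind = TRUE)
            d <- sqrt(min((idx[, 1L] - r)^2 + (idx[, 2L] - c)^2))
            if (d < best) { best <- d; bestLab <- k }
        }
        if (best <= radiusPx) out[r, c] <- bestLab
    }
    out
}

## exact two-sided signed-rank p-value by full enumeration of sign vectors
enumWilcoxon <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- as.numeric(signs %*% r)
    pLow <- mean(W <= V + 1e-9)
    pHigh <- mean(W >= V - 1e-9)
    min(1, 2 * min(pLow, pHigh))
}

## small deterministic phantom shared by several tests
smallPhantom <- function(seed = 7L, nCells = 120L, ...) {
    generatePhantomImage(phantomConfig(imageSize = c(320L, 320L),
                                       nCells = nCells, seed = seed, ...))
}
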