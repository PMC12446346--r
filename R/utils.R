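## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards so library code never clobbers user streams.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        }, add = TRUE)
        set.seed(as.integer(seed))
    }
    force(expr)
}

## Derive a reproducible child seed from a base seed and a stage offset,
## keeping the result inside the 32-bit integer range.
childSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

## strip an EBImage Image down to a plain numeric matrix
.im2mat <- function(img) {
    m <- EBImage::imageData(img)
    dim(m) <- dim(m)[1:2]
    m
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name))
    if (positive && x <= 0)
        stop(sprintf("'%s' must be > 0", name))
    invisible(x)
}
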