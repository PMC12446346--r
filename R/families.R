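## Registry of the candidate non-negative distribution families used for
## histogram fitting and percentile mapping.  Each entry provides a
## maximum-likelihood fit plus density / CDF / quantile functions on the
## original data scale.  Parameter estimation is MLE; the least-squares
## criterion against the histogram governs model SELECTION only.

#' Candidate distribution families
#'
#' Names of the non-negative families available to [fitDistribution()]:
#' log-normal, Wald (inverse Gaussian), Burr (type XII, with scale), beta
#' (rescaled to the data range) and gamma.
#'
#' @return character vector of family names.
#' @export
#' @examples
#' distributionFamilies()
distributionFamilies <- function()
    c("lognormal", "wald", "burr", "beta", "gamma")

## ---- Wald / inverse Gaussian --------------------------------------------

.dwald <- function(x, mean, shape, log = FALSE) {
    lv <- ifelse(x > 0,
        0.5 * (log(shape) - log(2 * pi) - 3 * log(x)) -
            shape * (x - mean)^2 / (2 * mean^2 * x),
        -Inf)
    if (log) lv else exp(lv)
}

.pwald <- function(q, mean, shape) {
    ifelse(q <= 0, 0, {
        a <- sqrt(shape / q) * (q / mean - 1)
        b <- -sqrt(shape / q) * (q / mean + 1)
        ## second term computed in log space: exp(2*shape/mean) overflows
        pnorm(a) + exp(2 * shape / mean + pnorm(b, log.p = TRUE))
    })
}

.qwald <- function(p, mean, shape) {
    vapply(p, function(pp) {
        if (pp <= 0 || pp >= 1)
            stop("wald quantile requires p in (0, 1)")
        ## bracket by doubling around the mean, then uniroot + Newton polish
        lo <- mean; hi <- mean
        while (.pwald(lo, mean, shape) > pp && lo > .Machine$double.xmin)
            lo <- lo / 2
        while (.pwald(hi, mean, shape) < pp && hi < .Machine$double.xmax / 4)
            hi <- hi * 2
        x <- uniroot(function(x) .pwald(x, mean, shape) - pp, c(lo, hi),
                     tol = 1e-12 * mean)$root
        for (i in 1:4) {
            f <- .pwald(x, mean, shape) - pp
            d <- .dwald(x, mean, shape)
            if (d <= 0) break
            step <- f / d
            xn <- x - step
            if (xn <= 0) break
            x <- xn
            if (abs(step) < 1e-15 * x) break
        }
        x
    }, numeric(1L))
}

.fitWald <- function(x) {
    mu <- mean(x)
    lambda <- length(x) / sum(1 / x - 1 / mu)
    if (!is.finite(lambda) || lambda <= 0) stop("wald MLE degenerate")
    c(mean = mu, shape = lambda)
}

## ---- Burr XII ------------------------------------------------------------

.dburr <- function(x, shape1, shape2, scale, log = FALSE) {
    lv <- ifelse(x > 0, {
        z <- x / scale
        log(shape1) + log(shape2) - log(scale) + (shape1 - 1) * log(z) -
            (shape2 + 1) * log1p(z^shape1)
    }, -Inf)
    if (log) lv else exp(lv)
}

.pburr <- function(q, shape1, shape2, scale)
    ifelse(q <= 0, 0, -expm1(-shape2 * log1p((q / scale)^shape1)))

.qburr <- function(p, shape1, shape2, scale) {
    if (any(p <= 0 | p >= 1)) stop("burr quantile requires p in (0, 1)")
    scale * expm1(-log1p(-p) / shape2)^(1 / shape1)
}

.fitBurr <- function(x) {
    nll <- function(par) {
        s1 <- exp(par[1L]); s2 <- exp(par[2L]); sc <- exp(par[3L])
        -sum(.dburr(x, s1, s2, sc, log = TRUE))
    }
    init <- c(log(2), log(1), log(median(x)))
    fit <- optim(init, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    if (!is.finite(fit$value)) stop("burr fit did not converge")
    p <- exp(fit$par)
    c(shape1 = p[1L], shape2 = p[2L], scale = p[3L])
}

## ---- beta with scale extension ------------------------------------------

.fitBeta <- function(x) {
    ## support [0, scale]; scale fixed just above the sample maximum so the
    ## likelihood is finite, shapes then fitted by MLE
    scale <- max(x) * (1 + 1 / length(x))
    y <- x / scale
    y <- pmin(pmax(y, .Machine$double.eps), 1 - .Machine$double.eps)
    m <- mean(y); v <- var(y)
    common <- max(m * (1 - m) / v - 1, 1e-3)
    init <- log(c(max(m * common, 1e-3), max((1 - m) * common, 1e-3)))
    nll <- function(par)
        -sum(dbeta(y, exp(par[1L]), exp(par[2L]), log = TRUE))
    fit <- optim(init, nll, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-10))
    c(shape1 = exp(fit$par[1L]), shape2 = exp(fit$par[2L]), scale = scale)
}

## ---- gamma ---------------------------------------------------------------

.fitGamma <- function(x) {
    ## gamma is scale-equivariant: fit on unit-mean data for stable optim,
    ## then rescale the rate
    s <- mean(x)
    y <- x / s
    v <- var(y)
    start <- list(shape = 1 / v, rate = 1 / v)
    fit <- suppressWarnings(MASS::fitdistr(y, "gamma", start = start,
                                           lower = c(1e-10, 1e-10)))
    est <- fit$estimate
    c(shape = unname(est[["shape"]]), rate = unname(est[["rate"]]) / s)
}

## ---- registry ------------------------------------------------------------

.familyRegistry <- list(
    lognormal = list(
        fit = function(x) {
            lx <- log(x[x > 0])
            if (length(lx) < 2L) stop("lognormal needs positive values")
            mu <- mean(lx)
            c(meanlog = mu, sdlog = sqrt(mean((lx - mu)^2)))
        },
        d = function(x, p) dlnorm(x, p[["meanlog"]], p[["sdlog"]]),
        p = function(q, p) plnorm(q, p[["meanlog"]], p[["sdlog"]]),
        q = function(pr, p) qlnorm(pr, p[["meanlog"]], p[["sdlog"]])),
    wald = list(
        fit = .fitWald,
        d = function(x, p) .dwald(x, p[["mean"]], p[["shape"]]),
        p = function(q, p) .pwald(q, p[["mean"]], p[["shape"]]),
        q = function(pr, p) .qwald(pr, p[["mean"]], p[["shape"]])),
    burr = list(
        fit = .fitBurr,
        d = function(x, p) .dburr(x, p[["shape1"]], p[["shape2"]], p[["scale"]]),
        p = function(q, p) .pburr(q, p[["shape1"]], p[["shape2"]], p[["scale"]]),
        q = function(pr, p) .qburr(pr, p[["shape1"]], p[["shape2"]], p[["scale"]])),
    beta = list(
        fit = .fitBeta,
        d = function(x, p) ifelse(x >= 0 & x <= p[["scale"]],
            dbeta(x / p[["scale"]], p[["shape1"]], p[["shape2"]]) / p[["scale"]], 0),
        p = function(q, p) pbeta(pmin(pmax(q / p[["scale"]], 0), 1),
                                 p[["shape1"]], p[["shape2"]]),
        q = function(pr, p) qbeta(pr, p[["shape1"]], p[["shape2"]]) * p[["scale"]]),
    gamma = list(
        fit = .fitGamma,
        d = function(x, p) dgamma(x, p[["shape"]], p[["rate"]]),
        p = function(q, p) pgamma(q, p[["shape"]], p[["rate"]]),
        q = function(pr, p) qgamma(pr, p[["shape"]], p[["rate"]])))

.getFamily <- function(name) {
    fam <- .familyRegistry[[name]]
    if (is.null(fam)) stop(sprintf("unknown distribution family '%s'", name))
    fam
}
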