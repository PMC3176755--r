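#' @include AllClasses.R
NULL

#' Estimate convolution background parameters for one array
#'
#' Heuristic moment/mode estimates of the RMA convolution model
#' `O = S + B`, `S ~ Exp(alpha)` (truncated at 0), `B ~ N(mu, sigma^2)`,
#' from one array's raw intensities: `mu` is the kernel-density maximizer of
#' the lower half of the data, `sigma` the half-normal spread of values
#' below the mode (times `sqrt(2)`), and `alpha` the reciprocal mean
#' exceedance above the mode.
#'
#' @param x numeric vector of raw intensities of one array.
#' @return named numeric vector `c(mu, sigma, alpha)`.
#' @export
estimateBackgroundParameters <- function(x) {
    if (length(unique(x)) < 2L)
        stop("degenerate array: constant intensities")
    dmode <- function(v) {
        d <- stats::density(v, kernel = "epanechnikov", n = 2^14)
        d$x[which.max(d$y)]
    }
    ## two-pass mode: raw intensities are heavily right-skewed (a density
    ## grid over the full range is too coarse near the background bulk),
    ## so the mode is first localized on the log scale and then
    ## re-estimated on the raw sub-mode values only
    m1 <- 2^dmode(log2(x))
    below <- x[x < m1]
    mu <- if (length(below) >= 2L) dmode(below) else m1
    bg <- x[x < mu]
    if (length(bg) < 2L) bg <- below
    sigma <- sqrt(sum((bg - mu)^2) / (length(bg) - 1L)) * sqrt(2)
    above <- x[x > mu]
    alpha <- 1 / mean(above - mu)
    c(mu = mu, sigma = sigma, alpha = alpha)
}

#' Background-correct raw intensities (normal + exponential convolution)
#'
#' Per array, replaces each observed intensity `o` by the conditional
#' expectation `E[S | O = o]` under the convolution model `O = S + B` with
#' `S ~ Exp(alpha)` truncated at zero and `B ~ N(mu, sigma^2)`, parameters
#' estimated per array by [estimateBackgroundParameters()] unless injected.
#' The transform is strictly positive and strictly increasing in the input.
#'
#' @param x a [ProbeIntensities] or a positive probe x array matrix.
#' @param params optional parameter override: a `c(mu, sigma, alpha)` vector
#'   applied to every array, or a list of such vectors (one per array).
#' @return object of the same class as `x` with corrected intensities.
#' @export
backgroundCorrect <- function(x, params = NULL) {
    if (is(x, "ProbeIntensities")) {
        m <- backgroundCorrect(intensities(x), params = params)
        return(probeIntensities(m, arrayInfo = as.data.frame(arrayInfo(x))))
    }
    m <- as.matrix(x)
    if (!is.null(params) && !is.list(params))
        params <- rep(list(params), ncol(m))
    out <- m
    for (a in seq_len(ncol(m))) {
        p <- if (is.null(params)) estimateBackgroundParameters(m[, a])
             else params[[a]]
        ## normexp parametrizes the exponential by its mean 1/alpha
        out[, a] <- limma::normexp.signal(
            par = c(p[[1]], log(p[[2]]), -log(p[[3]])), x = m[, a])
    }
    out
}

#' Quantile-normalize arrays to a common distribution
#'
#' After normalization every column's sorted values equal the across-array
#' mean of sorted values; tied values receive the mean of their rank means.
#' A single array is returned unchanged and the operation is idempotent.
#'
#' @param x matrix (probes x arrays) or [ProbeIntensities].
#' @return same class as `x`, normalized.
#' @export
quantileNormalize <- function(x) {
    if (is(x, "ProbeIntensities"))
        return(probeIntensities(quantileNormalize(intensities(x)),
                                arrayInfo = as.data.frame(arrayInfo(x))))
    m <- as.matrix(x)
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

#' Median polish of one probeset block
#'
#' Tukey median polish of a probes x arrays block of log2 intensities:
#' alternating row and column median sweeps (rows first) until the largest
#' absolute sweep median falls below `tol` or `maxIter` full sweeps are
#' done. The probeset expression per array is `overall + arrayEffect`.
#'
#' @param block numeric matrix, probes x arrays, finite.
#' @param tol convergence tolerance on sweep medians (default 0.01).
#' @param maxIter maximum full sweeps (default 10).
#' @return list with `overall`, `probeEffects`, `arrayEffects`,
#'   `residuals`, `expression` (= overall + arrayEffects), `iterations`,
#'   `converged`.
#' @export
medianPolish <- function(block, tol = 0.01, maxIter = 10L) {
    z <- as.matrix(block)
    if (!all(is.finite(z))) stop("non-finite values in probeset block")
    nr <- nrow(z); nc <- ncol(z)
    overall <- 0
    r <- numeric(nr); cc <- numeric(nc)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        rdelta <- apply(z, 1L, stats::median)
        z <- z - rdelta
        r <- r + rdelta
        delta <- stats::median(cc)
        overall <- overall + delta
        cc <- cc - delta
        cdelta <- apply(z, 2L, stats::median)
        z <- sweep(z, 2L, cdelta)
        cc <- cc + cdelta
        delta <- stats::median(r)
        overall <- overall + delta
        r <- r - delta
        if (max(abs(rdelta)) < tol && max(abs(cdelta)) < tol) {
            converged <- TRUE
            break
        }
    }
    expr <- overall + cc
    names(expr) <- colnames(block)
    list(overall = overall, probeEffects = stats::setNames(r, rownames(block)),
         arrayEffects = stats::setNames(cc, colnames(block)),
         residuals = z, expression = expr, iterations = iter,
         converged = converged)
}

#' Background-corrected, quantile-normalized log2 probe matrix
#'
#' The shared preprocessing pass of the RMA pipeline, exposed so that real
#' probesets and resampled negative pseudo-probesets can be summarized from
#' the identical normalized data (a single normalization over all probes on
#' the array, negative probes included).
#'
#' @param x a [ProbeIntensities].
#' @param bgParams optional background parameter override, see
#'   [backgroundCorrect()].
#' @return log2 matrix, probes x arrays.
#' @export
normalizedProbeMatrix <- function(x, bgParams = NULL) {
    m <- backgroundCorrect(intensities(x), params = bgParams)
    log2(quantileNormalize(m))
}

.probesetExpression <- function(values, info, method) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(info))
    new("ProbesetExpression", se, method = method)
}

#' RMA expression summarization
#'
#' Background correction ([backgroundCorrect()]), quantile normalization,
#' log2 transform, then per-probeset median polish; probeset expression is
#' `overall + arrayEffect`. Only probes of retained probesets are
#' summarized, but the normalization pass runs over the full probe matrix
#' (negative probes included), so detection nulls share it.
#'
#' @param x a [ProbeIntensities].
#' @param annotation a [ProbesetAnnotation].
#' @param bgParams optional background parameter override.
#' @return a [ProbesetExpression] with method tag `"rma"`.
#' @export
rmaSummarize <- function(x, annotation, bgParams = NULL) {
    probes <- unlist(annotation@probesetProbes, use.names = FALSE)
    missing <- setdiff(probes, rownames(x))
    if (length(missing))
        stop("annotation references probes missing from the matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) " ...")
    l2 <- normalizedProbeMatrix(x, bgParams = bgParams)
    sets <- annotation@probesetProbes
    vals <- matrix(NA_real_, length(sets), ncol(l2),
                   dimnames = list(names(sets), colnames(l2)))
    for (ps in names(sets))
        vals[ps, ] <- medianPolish(l2[sets[[ps]], , drop = FALSE])$expression
    .probesetExpression(vals, as.data.frame(arrayInfo(x)), "rma")
}

## Alternating least-squares fit of the multiplicative model x_ja =
## phi_j * theta_a with identifiability constraint sum(phi^2) = J.
.fitMbei <- function(x, tol = 1e-10, maxIter = 200L) {
    J <- nrow(x)
    theta <- colMeans(x)
    if (all(theta == 0)) theta <- rep(1, ncol(x))
    phi <- rep(1, J)
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        phi <- as.vector(x %*% theta) / sum(theta^2)
        s <- sqrt(sum(phi^2) / J)
        if (s == 0) break
        phi <- phi / s
        thetaNew <- as.vector(crossprod(x, phi)) / J
        if (sum(phi) < 0) { phi <- -phi; thetaNew <- -thetaNew }
        delta <- max(abs(thetaNew - theta)) /
            max(max(abs(theta)), .Machine$double.eps)
        theta <- thetaNew
        if (delta < tol) { converged <- TRUE; break }
    }
    list(phi = phi, theta = theta, converged = converged)
}

#' Model-based expression index (Li-Wong type) summarization
#'
#' Per probeset, fits the multiplicative model
#' `PM_ja = phi_j * theta_a + error` by alternating least squares under the
#' identifiability constraint `sum(phi_j^2) = J` (PM-only; this data model
#' has no mismatch probes). After convergence, probes whose largest
#' standardized residual exceeds 3 are down-weighted to zero once and the
#' model refitted. Returns `log2(theta_a)` per array. Arrays are
#' quantile-normalized beforehand (`normalize = TRUE`).
#'
#' @param x a [ProbeIntensities] (>= 2 arrays).
#' @param annotation a [ProbesetAnnotation].
#' @param normalize quantile-normalize arrays first (default `TRUE`).
#' @param tol,maxIter alternating least-squares controls; non-convergence
#'   yields a warning and the last iterate.
#' @return a [ProbesetExpression] with method tag `"mbei"`.
#' @export
mbeiSummarize <- function(x, annotation, normalize = TRUE, tol = 1e-10,
                          maxIter = 200L) {
    if (ncol(x) < 2L) stop("the model needs at least 2 arrays")
    m <- intensities(x)
    if (normalize) m <- quantileNormalize(m)
    sets <- annotation@probesetProbes
    missing <- setdiff(unlist(sets, use.names = FALSE), rownames(m))
    if (length(missing))
        stop("annotation references probes missing from the matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    vals <- matrix(NA_real_, length(sets), ncol(m),
                   dimnames = list(names(sets), colnames(m)))
    nonConv <- character(0)
    for (ps in names(sets)) {
        block <- m[sets[[ps]], , drop = FALSE]
        fit <- .fitMbei(block, tol = tol, maxIter = maxIter)
        resid <- block - outer(fit$phi, fit$theta)
        s <- stats::sd(resid)
        if (is.finite(s) && s > 0 && nrow(block) > 1L) {
            bad <- apply(abs(resid) / s, 1L, max) > 3
            if (any(bad) && !all(bad)) {
                fit <- .fitMbei(block[!bad, , drop = FALSE], tol = tol,
                                maxIter = maxIter)
            }
        }
        if (!fit$converged) nonConv <- c(nonConv, ps)
        vals[ps, ] <- log2(pmax(fit$theta, .Machine$double.eps))
    }
    if (length(nonConv))
        warning("model fit did not converge for ", length(nonConv),
                " probeset(s); last iterate used")
    .probesetExpression(vals, as.data.frame(arrayInfo(x)), "mbei")
}
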