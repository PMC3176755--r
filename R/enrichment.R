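#' @include AllClasses.R
NULL

#' Fit per-gene group means with pooled residual variance
#'
#' Cell-means linear model per gene: one mean per sample group, residual
#' variance pooled across groups with `df = sum(n_g - 1)` degrees of
#' freedom (equivalent to per-gene ordinary least squares on a one-way
#' design).
#'
#' @param expr a [ProbesetExpression] or genes x arrays log2 matrix.
#' @param groups factor or character vector, one label per array; defaults
#'   to the `tissue` column of the array metadata when `expr` is a
#'   [ProbesetExpression].
#' @return list with `means` (genes x groups), `s2` (pooled residual
#'   variance per gene), `df` (residual degrees of freedom) and
#'   `groupSizes`.
#' @export
fitGroups <- function(expr, groups = NULL) {
    e <- if (is(expr, "ProbesetExpression")) {
        if (is.null(groups)) groups <- arrayInfo(expr)$tissue
        exprValues(expr)
    } else as.matrix(expr)
    groups <- as.factor(groups)
    if (length(groups) != ncol(e))
        stop("one group label per array is required")
    sizes <- table(groups)
    df <- sum(sizes - 1L)
    if (df < 1L) stop("no residual degrees of freedom (df = 0)")
    means <- vapply(levels(groups), function(g)
        rowMeans(e[, groups == g, drop = FALSE]), numeric(nrow(e)))
    if (nrow(e) == 1L)
        means <- matrix(means, nrow = 1L,
                        dimnames = list(rownames(e), levels(groups)))
    rss <- rowSums((e - means[, as.character(groups), drop = FALSE])^2)
    list(means = means, s2 = rss / df, df = df,
         groupSizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by bisection to relative tolerance
#' 1e-8; `x <= 0` returns `Inf` (no finite solution).
#'
#' @param x positive numeric.
#' @return numeric `y` with `trigamma(y) = x`.
#' @export
trigammaInverse <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi) || xi <= 0) return(Inf)
        lo <- 1e-8; hi <- 1e8
        if (trigamma(lo) < xi) return(lo)
        if (trigamma(hi) > xi) return(hi)
        for (i in seq_len(200L)) {
            mid <- sqrt(lo * hi)
            if (trigamma(mid) > xi) lo <- mid else hi <- mid
            if ((hi - lo) / hi < 1e-8) break
        }
        sqrt(lo * hi)
    }, numeric(1))
}

#' Empirical-Bayes variance moderation
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' a scaled inverse-chi-square prior on the per-gene residual variances by
#' method of moments on `log s^2` (digamma/trigamma matching), then forms
#' the posterior variances `s~^2 = (d0 s0^2 + df s^2) / (d0 + df)`. When
#' the moment equation has no positive solution (e.g. all `s^2` identical)
#' the prior df is infinite and variances shrink fully to `s0^2`, with a
#' warning. Both hyperparameters can be injected for testing.
#'
#' @param fit result of [fitGroups()].
#' @param d0,s02 optional hyperparameter overrides.
#' @return list with `d0`, `s02`, `sTilde2` (posterior variances), `dfPrior`
#'   + `dfResidual` and `dfTotal` used for the moderated statistics.
#' @export
ebayesShrink <- function(fit, d0 = NULL, s02 = NULL) {
    s2 <- fit$s2; df <- fit$df
    if (is.null(d0) || is.null(s02)) {
        pos <- s2 > 0
        if (sum(pos) < 10L)
            stop("need at least 10 genes with positive residual variance")
        eg <- log(s2[pos]) - digamma(df / 2) + log(df / 2)
        n <- length(eg)
        evar <- mean((eg - mean(eg))^2) * n / (n - 1L) - trigamma(df / 2)
        if (is.finite(evar) && evar > 0) {
            est.d0 <- 2 * trigammaInverse(evar)
            est.s02 <- exp(mean(eg) + digamma(est.d0 / 2) -
                           log(est.d0 / 2))
        } else {
            warning("residual variances carry no excess spread; ",
                    "shrinking fully (d0 = Inf)")
            est.d0 <- Inf
            est.s02 <- exp(mean(eg))
        }
        if (is.null(d0)) d0 <- est.d0
        if (is.null(s02)) s02 <- est.s02
    }
    sTilde2 <- if (is.infinite(d0)) rep(s02, length(s2))
               else (d0 * s02 + df * s2) / (d0 + df)
    names(sTilde2) <- names(s2)
    list(d0 = d0, s02 = s02, sTilde2 = sTilde2, dfPrior = d0,
         dfResidual = df, dfTotal = d0 + df)
}

#' Moderated t statistics for one-vs-one group contrasts
#'
#' For each contrast `target - other`:
#' `t = (m_target - m_other) / (s~ sqrt(1/n_target + 1/n_other))` on
#' `d0 + df` degrees of freedom, two-sided p from the t distribution.
#'
#' @param fit result of [fitGroups()].
#' @param shrink result of [ebayesShrink()].
#' @param target target group name.
#' @param others character vector of comparison groups (default: all other
#'   groups in the fit).
#' @return data.frame with columns `gene`, `contrast`, `logFC`, `t`, `p`.
#' @export
moderatedContrasts <- function(fit, shrink, target, others = NULL) {
    gl <- colnames(fit$means)
    if (is.null(others)) others <- setdiff(gl, target)
    if (target %in% others) stop("target group may not be among 'others'")
    if (!length(others)) stop("at least one comparison group is required")
    stopifnot(all(c(target, others) %in% gl))
    sT <- sqrt(shrink$sTilde2)
    genes <- rownames(fit$means)
    do.call(rbind, lapply(others, function(o) {
        se <- sT * sqrt(1 / fit$groupSizes[[target]] +
                        1 / fit$groupSizes[[o]])
        logFC <- fit$means[, target] - fit$means[, o]
        t <- logFC / se
        data.frame(gene = genes,
                   contrast = paste0(target, "-", o),
                   logFC = logFC, t = t,
                   p = 2 * stats::pt(-abs(t), df = shrink$dfTotal),
                   row.names = NULL)
    }))
}

#' Moderated F statistic across groups
#'
#' One-way F with the moderated denominator:
#' `F = [sum_g n_g (m_g - m.)^2 / (G - 1)] / s~^2` on `(G - 1, d0 + df)`
#' degrees of freedom, where `m.` is the size-weighted grand mean.
#'
#' @param fit result of [fitGroups()].
#' @param shrink result of [ebayesShrink()].
#' @param groups optional subset of group names (default all).
#' @return data.frame with columns `gene`, `F`, `p`.
#' @export
moderatedF <- function(fit, shrink, groups = NULL) {
    if (is.null(groups)) groups <- colnames(fit$means)
    m <- fit$means[, groups, drop = FALSE]
    n <- fit$groupSizes[groups]
    grand <- as.vector(m %*% n) / sum(n)
    num <- rowSums(sweep((m - grand)^2, 2L, n, `*`)) / (length(groups) - 1L)
    Fstat <- num / shrink$sTilde2
    data.frame(gene = rownames(fit$means), F = Fstat,
               p = stats::pf(Fstat, length(groups) - 1L, shrink$dfTotal,
                             lower.tail = FALSE),
               row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `adj_i = min_{j >= rank(i)} m p_(j) / j`, capped at 1, ties stable.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pvalues) {
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Prefilter genes by detection evidence
#'
#' Keeps genes with an array-level present call (`p <= threshold`) on at
#' least `minPresentArrays` of the arrays in the comparison.
#'
#' @param detection a [DetectionResult] or a probesets x arrays p-value
#'   matrix.
#' @param arrays optional character vector restricting to the comparison's
#'   arrays.
#' @param minPresentArrays minimum present arrays (default 3).
#' @param threshold presence threshold; defaults to the one stored in the
#'   [DetectionResult].
#' @return character vector of retained gene/probeset ids.
#' @export
prefilterByDetection <- function(detection, arrays = NULL,
                                 minPresentArrays = 3L, threshold = NULL) {
    p <- if (is(detection, "DetectionResult")) {
        if (is.null(threshold)) threshold <- detection@threshold
        detectionPvalues(detection)
    } else as.matrix(detection)
    if (is.null(threshold)) threshold <- 0.02
    if (!is.null(arrays)) {
        if (!all(arrays %in% colnames(p)))
            stop("detection calls do not cover all comparison arrays")
        p <- p[, arrays, drop = FALSE]
    }
    rownames(p)[rowSums(p <= threshold) >= minPresentArrays]
}

#' Genes enriched in the target group in every contrast
#'
#' Runs the group fit, variance moderation, and per-contrast moderated t
#' tests of the target group against each comparison group, adjusts
#' p-values per contrast (Benjamini-Hochberg across genes), and applies one
#' of two selection rules:
#'
#' * `"atlas"`: enriched when the adjusted p-value is below `alpha`
#'   (default 0.01) *and* the log fold change is positive in every
#'   contrast.
#' * `"gametophyte"`: a moderated-F gate first (BH-adjusted F p below
#'   `fAlpha`, default 0.05), then per-contrast up-significance (adjusted
#'   p below `fAlpha`, positive log fold change) in every contrast.
#'
#' @param expr a [ProbesetExpression] or genes x arrays matrix.
#' @param target target group name.
#' @param groups group labels per array (defaults to tissue metadata).
#' @param others comparison groups (default: all others).
#' @param alpha per-contrast adjusted-p cutoff for the atlas rule.
#' @param fAlpha FDR level of the gametophyte rule.
#' @param rule `"atlas"` or `"gametophyte"`.
#' @return list with `contrasts` (long data.frame: gene, contrast, logFC,
#'   t, p, adj_p), `verdicts` (data.frame: gene, enriched, rule) and the
#'   fitted `shrink` hyperparameters.
#' @export
enrichedInAllContrasts <- function(expr, target, groups = NULL,
        others = NULL, alpha = 0.01, fAlpha = 0.05,
        rule = c("atlas", "gametophyte")) {
    rule <- match.arg(rule)
    fit <- fitGroups(expr, groups)
    shrink <- ebayesShrink(fit)
    if (is.null(others)) others <- setdiff(colnames(fit$means), target)
    if (target %in% others) stop("target group may not be among 'others'")
    ct <- moderatedContrasts(fit, shrink, target, others)
    ct$adj_p <- stats::ave(ct$p, ct$contrast, FUN = bhAdjust)
    genes <- rownames(fit$means)
    if (rule == "atlas") {
        ok <- ct$adj_p < alpha & ct$logFC > 0
        enriched <- tapply(ok, factor(ct$gene, levels = genes), all)
        tag <- sprintf("atlas-%g-all", alpha)
    } else {
        Ftab <- moderatedF(fit, shrink, groups = c(target, others))
        gate <- stats::setNames(bhAdjust(Ftab$p) < fAlpha, Ftab$gene)
        ok <- ct$adj_p < fAlpha & ct$logFC > 0
        upAll <- tapply(ok, factor(ct$gene, levels = genes), all)
        enriched <- gate[genes] & upAll
        tag <- sprintf("gametophyte-FDR%g-all%d", fAlpha, length(others))
    }
    list(contrasts = ct,
         verdicts = data.frame(gene = genes,
                               enriched = as.logical(enriched[genes]),
                               rule = tag, row.names = NULL),
         shrink = shrink[c("d0", "s02")])
}
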