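#' @include AllClasses.R
NULL

#' Resample negative pseudo-probesets from the pool
#'
#' Draws `nSets` pseudo-probesets of `setSize` distinct probes per repeat,
#' uniformly without replacement within a set and with replacement across
#' sets, for `nRepeats` independent repeats. Fully seed-deterministic.
#'
#' @param pool a [NegativeProbePool] (or character vector of probe ids).
#' @param setSize probes per pseudo-probeset (default 11).
#' @param nSets pseudo-probesets per repeat (default 2000).
#' @param nRepeats independent resampling repeats (default 20).
#' @param seed integer seed.
#' @return list of length `nRepeats`; each element an `nSets x setSize`
#'   character matrix of probe ids.
#' @export
sampleNegativeProbesets <- function(pool, setSize = 11L, nSets = 2000L,
                                    nRepeats = 20L, seed = 1L) {
    ids <- if (is(pool, "NegativeProbePool")) negativeProbeIds(pool)
           else as.character(pool)
    if (length(ids) < setSize)
        stop("negative pool (", length(ids),
             ") smaller than setSize (", setSize, ")")
    set.seed(as.integer(seed))
    lapply(seq_len(nRepeats), function(r) {
        t(vapply(seq_len(nSets),
                 function(i) sample(ids, setSize),
                 character(setSize)))
    })
}

#' Summarize negative pseudo-probesets into null signals
#'
#' Each pseudo-probeset is summarized exactly like a real probeset on the
#' RMA path: median polish of its probes' rows of the shared
#' background-corrected, quantile-normalized log2 matrix (see
#' [normalizedProbeMatrix()]; real and pseudo probesets share one
#' normalization pass).
#'
#' @param samples list of pseudo-probeset matrices from
#'   [sampleNegativeProbesets()].
#' @param x a [ProbeIntensities] containing all pool probes, or a
#'   precomputed normalized log2 probe matrix.
#' @param method summarization used for the null; anything but `"rma"`
#'   warns (the detection null is defined on the RMA path).
#' @param bgParams optional background parameter override.
#' @return list (one per repeat) of `nSets x arrays` numeric matrices of
#'   log2 null signals.
#' @export
nullSignals <- function(samples, x, method = "rma", bgParams = NULL) {
    if (!identical(method, "rma"))
        warning("detection null is defined on the RMA path; got '",
                method, "'")
    l2 <- if (is(x, "ProbeIntensities"))
              normalizedProbeMatrix(x, bgParams = bgParams)
          else as.matrix(x)
    probes <- unique(unlist(samples, use.names = FALSE))
    if (!all(probes %in% rownames(l2)))
        stop("pool probes missing from the intensity matrix")
    lapply(samples, function(sets) {
        out <- matrix(NA_real_, nrow(sets), ncol(l2),
                      dimnames = list(NULL, colnames(l2)))
        if (ncol(l2) == 1L) {
            ## one array: median polish of a J x 1 block reduces to the
            ## median of its values
            v <- l2[, 1L]
            out[, 1L] <- apply(matrix(v[t(sets)], ncol = nrow(sets)), 2L,
                               stats::median)
        } else {
            for (i in seq_len(nrow(sets)))
                out[i, ] <- medianPolish(
                    l2[sets[i, ], , drop = FALSE])$expression
        }
        out
    })
}

#' Empirical detection p-values against the negative-probeset null
#'
#' Per array and probeset signal `x`, each resampling repeat contributes
#' `p = (#{null >= x} + 1) / (nSets + 1)` against that array's null
#' signals (upper tail, add-one smoothing so p never reaches 0); the
#' repeats' p-values are averaged arithmetically.
#'
#' @param expr a [ProbesetExpression] or probesets x arrays log2 matrix.
#' @param null list of null-signal matrices from [nullSignals()]; each must
#'   hold at least 100 sets and cover the same arrays as `expr`.
#' @return numeric matrix of averaged p-values, probesets x arrays.
#' @export
detectionPValues <- function(expr, null) {
    e <- if (is(expr, "ProbesetExpression")) exprValues(expr)
         else as.matrix(expr)
    if (!length(null)) stop("no null repeats supplied")
    for (nm in null) {
        if (!identical(colnames(nm), colnames(e)))
            stop("array mismatch between expression and null signals")
        if (nrow(nm) < 100L)
            stop("need at least 100 null sets per array")
    }
    acc <- matrix(0, nrow(e), ncol(e), dimnames = dimnames(e))
    for (nm in null) {
        n <- nrow(nm)
        for (a in seq_len(ncol(e))) {
            sorted <- sort(nm[, a])
            ge <- n - findInterval(e[, a], sorted, left.open = TRUE)
            acc[, a] <- acc[, a] + (ge + 1) / (n + 1)
        }
    }
    acc / length(null)
}

#' Present/marginal/absent calls per sample group
#'
#' An array-level present call is `p <= threshold`. A probeset is called
#' `P` in a group when present on at least `ceiling(presentFrac * R)` of
#' the group's `R` arrays, otherwise `M` when present on at least
#' `ceiling(marginalFrac * R)` arrays, otherwise `A`; the three categories
#' are exhaustive and mutually exclusive (`M` excludes `P`).
#'
#' @param pvalues probesets x arrays matrix of detection p-values.
#' @param groups factor or character vector, one group label per array.
#' @param threshold array-level presence threshold in (0, 1), default 0.02.
#' @param presentFrac,marginalFrac replicate fractions defining P and M
#'   (defaults 3/4 and 2/4, generalized to other replicate counts by
#'   ceiling).
#' @return character matrix probesets x groups with entries `"P"`, `"M"`,
#'   `"A"`.
#' @export
callPresence <- function(pvalues, groups, threshold = 0.02,
                         presentFrac = 3 / 4, marginalFrac = 2 / 4) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie in (0, 1)")
    groups <- as.factor(groups)
    if (length(groups) != ncol(pvalues))
        stop("one group label per array is required")
    if (any(table(groups) < 2L))
        stop("each group needs at least 2 arrays")
    calls <- matrix("A", nrow(pvalues), nlevels(groups),
                    dimnames = list(rownames(pvalues), levels(groups)))
    for (g in levels(groups)) {
        sub <- pvalues[, groups == g, drop = FALSE]
        R <- ncol(sub)
        nPresent <- rowSums(sub <= threshold)
        calls[nPresent >= ceiling(marginalFrac * R), g] <- "M"
        calls[nPresent >= ceiling(presentFrac * R), g] <- "P"
    }
    calls
}

#' Full detection-call pipeline
#'
#' Convenience wrapper: shared normalization pass, probeset summarization on
#' the RMA path, resampled negative-probeset null, averaged empirical
#' p-values, and per-group P/M/A calls.
#'
#' @param x a [ProbeIntensities].
#' @param annotation a [ProbesetAnnotation].
#' @param pool a [NegativeProbePool].
#' @param setSize,nSets,nRepeats,seed resampling controls, see
#'   [sampleNegativeProbesets()].
#' @param threshold presence threshold, see [callPresence()].
#' @param groups group labels per array; defaults to the `tissue` column of
#'   the array metadata.
#' @param bgParams optional background parameter override.
#' @return a [DetectionResult].
#' @export
detectAboveBackground <- function(x, annotation, pool, setSize = 11L,
        nSets = 2000L, nRepeats = 20L, threshold = 0.02, seed = 1L,
        groups = NULL, bgParams = NULL) {
    l2 <- normalizedProbeMatrix(x, bgParams = bgParams)
    sets <- annotation@probesetProbes
    vals <- matrix(NA_real_, length(sets), ncol(l2),
                   dimnames = list(names(sets), colnames(l2)))
    for (ps in names(sets))
        vals[ps, ] <- medianPolish(l2[sets[[ps]], , drop = FALSE])$expression
    samples <- sampleNegativeProbesets(pool, setSize = setSize,
                                       nSets = nSets, nRepeats = nRepeats,
                                       seed = seed)
    null <- nullSignals(samples, l2)
    p <- detectionPValues(vals, null)
    if (is.null(groups)) groups <- arrayInfo(x)$tissue
    calls <- callPresence(p, groups, threshold = threshold)
    new("DetectionResult", pvalues = p, calls = calls,
        threshold = threshold, nRepeats = as.integer(nRepeats))
}

#' Calibration of the detection call under the null
#'
#' Measures the empirical false-positive rate of array-level present calls
#' on one simulated array: `poolSize` negative-probe log2 signals are drawn
#' from the standard normal background, `nSets` pseudo-probesets of
#' `setSize` probes are resampled from that pool (`nRepeats` times,
#' p-values averaged), and `nProbesets` test probesets are simulated from
#' the *identical* background distribution and summarized the same way
#' (median polish of a single-array block). The returned rate is the
#' fraction of test probesets with averaged detection p at or below the
#' threshold; for a calibrated statistic it matches the threshold up to
#' Monte-Carlo error.
#'
#' @param nProbesets number of test probesets (default 10000).
#' @param poolSize negative-probe pool size (default 1574).
#' @param setSize,nSets,nRepeats resampling controls (defaults 11, 2000,
#'   20).
#' @param threshold present-call threshold (default 0.02).
#' @param seed integer seed.
#' @return list with `rate`, `threshold`, `se` (binomial Monte-Carlo
#'   standard error at the nominal rate) and `nProbesets`.
#' @export
detectionCalibration <- function(nProbesets = 10000L, poolSize = 1574L,
        setSize = 11L, nSets = 2000L, nRepeats = 20L, threshold = 0.02,
        seed = 1L) {
    set.seed(as.integer(seed))
    poolIds <- sprintf("neg%04d", seq_len(poolSize))
    l2 <- matrix(stats::rnorm(poolSize), ncol = 1L,
                 dimnames = list(poolIds, "array1"))
    test <- matrix(stats::rnorm(nProbesets * setSize), ncol = setSize)
    signal <- matrix(apply(test, 1L, stats::median), ncol = 1L,
                     dimnames = list(sprintf("ps%05d",
                                             seq_len(nProbesets)),
                                     "array1"))
    samples <- sampleNegativeProbesets(poolIds, setSize = setSize,
                                       nSets = nSets, nRepeats = nRepeats,
                                       seed = as.integer(seed) + 1L)
    null <- nullSignals(samples, l2)
    p <- detectionPValues(signal, null)
    list(rate = mean(p <= threshold), threshold = threshold,
         se = sqrt(threshold * (1 - threshold) / nProbesets),
         nProbesets = nProbesets)
}

#' Venn region counts for present-call sets
#'
#' Counts genes in every intersection region of two or more present-call
#' sets over a shared gene universe; the regions partition the union.
#'
#' @param sets named list (>= 2) of character vectors of gene ids.
#' @return data.frame with one row per non-empty membership pattern:
#'   logical columns (one per set) and `count`. Region counts sum to the
#'   size of the union.
#' @export
#' @examples
#' vennRegions(list(MMC = c("a", "b"), nucellus = c("b", "c")))
vennRegions <- function(sets) {
    if (length(sets) < 2L) stop("need at least two sets")
    if (is.null(names(sets)) || any(names(sets) == ""))
        names(sets) <- paste0("set", seq_along(sets))
    universe <- unique(unlist(sets, use.names = FALSE))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
        dimnames = list(NULL, names(sets)))
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
    names(patterns) <- names(sets)
    patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
    patterns$count <- apply(patterns, 1L, function(p)
        sum(colSums(t(member) == as.logical(p)) == length(sets)))
    rownames(patterns) <- apply(
        patterns[, names(sets), drop = FALSE], 1L,
        function(p) paste(names(sets)[as.logical(p)], collapse = "&"))
    patterns
}
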