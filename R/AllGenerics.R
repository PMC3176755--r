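#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers: `intensities()`
#' returns the raw probe x array matrix, `exprValues()` the summarized log2
#' matrix, `exprMethod()` the summarization tag, `arrayInfo()` the per-array
#' metadata, `detectionPvalues()` / `detectionCalls()` the two halves of a
#' [DetectionResult], and `negativeProbeIds()` the pool membership.
#'
#' @param x an MMCarray S4 object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("exprMethod", function(x) standardGeneric("exprMethod"))

#' @rdname accessors
#' @export
setGeneric("arrayInfo", function(x) standardGeneric("arrayInfo"))

#' @rdname accessors
#' @export
setGeneric("detectionPvalues", function(x) standardGeneric("detectionPvalues"))

#' @rdname accessors
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))

#' @rdname accessors
#' @export
setGeneric("negativeProbeIds", function(x) standardGeneric("negativeProbeIds"))

#' @rdname accessors
#' @export
setMethod("intensities", "ProbeIntensities", function(x)
    SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ProbesetExpression", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("exprMethod", "ProbesetExpression", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("arrayInfo", "SummarizedExperiment", function(x)
    SummarizedExperiment::colData(x))

#' @rdname accessors
#' @export
setMethod("detectionPvalues", "DetectionResult", function(x) x@pvalues)

#' @rdname accessors
#' @export
setMethod("presenceCalls", "DetectionResult", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("negativeProbeIds", "NegativeProbePool", function(x) x@probeIds)

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes x",
        object@probesPerSet, "probes;", object@nTissues, "tissues x",
        object@replicatesPerTissue, "replicates;",
        object@nNegativeProbes, "negative probes;",
        nrow(object@plantedEnriched), "planted enriched genes; seed",
        object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@expressed), "genes x",
        ncol(object@expressed), "tissues;",
        nrow(object@enriched), "planted enriched;",
        length(object@negativeProbeIds), "negative probes;",
        length(object@multimapProbeIds), "multimap probes\n")
})

setMethod("show", "ProbesetAnnotation", function(object) {
    cat("ProbesetAnnotation:", length(object@probesetGene),
        "retained probesets (", sum(lengths(object@probesetProbes)),
        "probes );", nrow(object@removedProbes), "probes removed;",
        length(object@removedProbesets), "probesets removed\n")
})

setMethod("show", "NegativeProbePool", function(object) {
    mm <- object@bestHitMismatches
    cat("NegativeProbePool:", length(object@probeIds), "probes (",
        sum(is.na(mm)), "without any hit at the search cap )\n")
})

setMethod("show", "DetectionResult", function(object) {
    tab <- table(factor(object@calls, levels = c("P", "M", "A")))
    cat("DetectionResult:", nrow(object@pvalues), "probesets x",
        ncol(object@pvalues), "arrays;", ncol(object@calls),
        "groups; threshold", object@threshold, ";",
        object@nRepeats, "repeats\n  group calls: P =", tab[["P"]],
        ", M =", tab[["M"]], ", A =", tab[["A"]], "\n")
})

setMethod("show", "CrossCounts", function(object) {
    cat("CrossCounts [", object@line, ",", object@direction, "]: het =",
        object@nHet, ", wt =", object@nWt, "\n")
})

setMethod("show", "GoDag", function(object) {
    cat("GoDag:", length(object@terms), "terms,",
        sum(lengths(object@parents)), "parent links,",
        if (length(object@propagated)) "annotations propagated"
        else "annotations not propagated", "\n")
})
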