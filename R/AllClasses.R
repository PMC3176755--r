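#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration for synthetic probe-level array data
#'
#' Holds all parameters of the synthetic-data generator: array geometry
#' (genes, probes per probeset, tissues, replicates), the intensity model
#' (additive Gaussian optical background plus exponential signal on the log2
#' scale, per-probe multiplicative affinities), planted tissue-enriched genes
#' of known log2 effect size, a pool of orphan ("negative") probes carrying
#' background only, and deliberately multi-mapping probes. A single integer
#' seed fixes all downstream randomness.
#'
#' @slot nGenes number of genes on the array.
#' @slot probesPerSet probes per probeset (default 11, the ATH1 convention).
#' @slot nTissues number of tissue groups in the atlas.
#' @slot replicatesPerTissue biological replicates per tissue (default 4).
#' @slot nNegativeProbes number of background-only probes to emit.
#' @slot plantedEnriched data.frame with columns `gene`, `tissue`, `effect`
#'   (log2 units) describing planted tissue-enriched genes.
#' @slot backgroundMean,backgroundSd mean and SD of the Gaussian optical
#'   background on the log2 scale.
#' @slot signalRate rate of the exponential expression-signal component
#'   (log2 scale); mean expressed signal above background is `1/signalRate`.
#' @slot affinitySd SD of the per-probe log2 affinity (array-invariant).
#' @slot nMultimapProbes number of probes planted as exact substrings of a
#'   second gene.
#' @slot probeLength probe length in nucleotides (default 25).
#' @slot geneLength transcript length in nucleotides.
#' @slot pExpressed probability that a non-planted gene is expressed in any
#'   given tissue (planted genes are expressed everywhere).
#' @slot seed integer seed fixing all randomness of the generator.
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer", probesPerSet = "integer", nTissues = "integer",
        replicatesPerTissue = "integer", nNegativeProbes = "integer",
        plantedEnriched = "data.frame",
        backgroundMean = "numeric", backgroundSd = "numeric",
        signalRate = "numeric", affinitySd = "numeric",
        nMultimapProbes = "integer", probeLength = "integer",
        geneLength = "integer", pExpressed = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(nGenes = object@nGenes, probesPerSet = object@probesPerSet,
             nTissues = object@nTissues,
             replicatesPerTissue = object@replicatesPerTissue,
             probeLength = object@probeLength, geneLength = object@geneLength)
    if (any(is.na(cnt)) || any(cnt <= 0L))
        msg <- c(msg, "all counts must be > 0")
    if (object@nNegativeProbes < 0L || object@nMultimapProbes < 0L)
        msg <- c(msg, "probe pool sizes must be >= 0")
    if (!is.finite(object@backgroundSd) || object@backgroundSd <= 0)
        msg <- c(msg, "backgroundSd must be > 0")
    if (!is.finite(object@signalRate) || object@signalRate <= 0)
        msg <- c(msg, "signalRate must be > 0")
    if (nrow(object@plantedEnriched) &&
        !all(c("gene", "tissue", "effect") %in% names(object@plantedEnriched)))
        msg <- c(msg, "plantedEnriched needs columns gene, tissue, effect")
    if (nrow(object@plantedEnriched) &&
        !all(is.finite(object@plantedEnriched$effect)))
        msg <- c(msg, "planted effect sizes must be finite")
    if (object@geneLength < object@probeLength * 2L + 60L)
        msg <- c(msg, "geneLength too short for probe placement")
    if (is.na(object@seed)) msg <- c(msg, "seed must be set")
    if (length(msg)) msg else TRUE
})

#' Ground truth emitted by the synthetic-data generator
#'
#' Machine-readable record of every planted fact: which gene is expressed in
#' which tissue, the planted enriched (gene, tissue, effect) triples, the ids
#' of background-only negative probes and of deliberately multi-mapping
#' probes, and the mapping from genomic contig to gene used for annotation.
#'
#' @slot expressed logical matrix, genes x tissues.
#' @slot enriched data.frame (`gene`, `tissue`, `effect`).
#' @slot negativeProbeIds,multimapProbeIds character vectors of probe ids.
#' @slot targetGene named character vector mapping genomic contig ids to gene
#'   ids (`NA` for decoy contigs).
#' @export
setClass("GroundTruth",
    representation(expressed = "matrix", enriched = "data.frame",
                   negativeProbeIds = "character",
                   multimapProbeIds = "character",
                   targetGene = "character"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!is.logical(object@expressed))
        msg <- c(msg, "expressed must be a logical gene x tissue matrix")
    if (nrow(object@enriched)) {
        idx <- cbind(match(object@enriched$gene, rownames(object@expressed)),
                     match(object@enriched$tissue, colnames(object@expressed)))
        if (any(is.na(idx)) || !all(object@expressed[idx]))
            msg <- c(msg,
                "planted enriched genes must be expressed in their target tissue")
    }
    if (length(msg)) msg else TRUE
})

#' Raw probe-level intensities
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' `"intensity"` (probes x arrays, strictly positive, no missing values) and
#' column metadata `tissue` and `replicate`.
#'
#' @export
setClass("ProbeIntensities", contains = "SummarizedExperiment")

setValidity("ProbeIntensities", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'intensity' is required")
    v <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(v)) msg <- c(msg, "intensities must not contain missing values")
    else if (any(v <= 0)) msg <- c(msg, "intensities must be > 0")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be unique")
    if (!all(c("tissue", "replicate") %in%
             names(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData needs 'tissue' and 'replicate'")
    if (length(msg)) msg else TRUE
})

#' Probeset-level log2 expression
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"exprs"`
#' (probesets x arrays, log2 units, finite) carrying the array metadata of
#' the source [ProbeIntensities] and a `method` tag (`"rma"` or `"mbei"`).
#'
#' @slot method character, the summarization method used.
#' @export
setClass("ProbesetExpression", contains = "SummarizedExperiment",
         representation(method = "character"))

setValidity("ProbesetExpression", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is required")
    if (!all(is.finite(SummarizedExperiment::assay(object, "exprs"))))
        msg <- c(msg, "expression values must be finite")
    if (!object@method %in% c("rma", "mbei"))
        msg <- c(msg, "method must be 'rma' or 'mbei'")
    if (length(msg)) msg else TRUE
})

#' Probeset annotation (custom CDF-like mapping)
#'
#' The probe-to-probeset mapping after removal of perfect multi-mappers, the
#' probeset-to-gene assignment, and a record of removed probes (with reason)
#' and removed probesets.
#'
#' @slot probesetGene named character: probeset id -> gene id.
#' @slot probesetProbes named list: probeset id -> ordered probe ids.
#' @slot removedProbes data.frame (`probe_id`, `reason`).
#' @slot removedProbesets character vector of dropped probeset ids.
#' @export
setClass("ProbesetAnnotation",
    representation(probesetGene = "character", probesetProbes = "list",
                   removedProbes = "data.frame",
                   removedProbesets = "character"))

setValidity("ProbesetAnnotation", function(object) {
    msg <- character()
    if (!identical(sort(names(object@probesetGene)),
                   sort(names(object@probesetProbes))))
        msg <- c(msg, "probesetGene and probesetProbes must cover the same sets")
    probes <- unlist(object@probesetProbes, use.names = FALSE)
    if (anyDuplicated(probes))
        msg <- c(msg, "a probe may not appear in two probesets")
    if (any(lengths(object@probesetProbes) == 0L))
        msg <- c(msg, "retained probesets must contain probes")
    if (length(msg)) msg else TRUE
})

#' Pool of background-only negative probes
#'
#' Probes unused by any retained probeset whose best sequence hit anywhere in
#' the target databases has more than two mismatches (or that have no hit at
#' all). Provenance records the best-hit mismatch count per probe (`NA` when
#' there is no hit at the search cap).
#'
#' @slot probeIds ordered character vector of pool members.
#' @slot bestHitMismatches named integer vector, `NA` = no hit found.
#' @export
setClass("NegativeProbePool",
    representation(probeIds = "character", bestHitMismatches = "integer"))

setValidity("NegativeProbePool", function(object) {
    msg <- character()
    if (length(object@probeIds) == 0L)
        msg <- c(msg, "negative-probe pool must be non-empty")
    if (!identical(names(object@bestHitMismatches), object@probeIds))
        msg <- c(msg, "provenance must be named by probeIds, in order")
    mm <- object@bestHitMismatches
    if (any(!is.na(mm) & mm <= 2L))
        msg <- c(msg, "pool members must have best-hit mismatches > 2")
    if (length(msg)) msg else TRUE
})

#' Detection p-values and present/marginal/absent calls
#'
#' Per-probeset per-array empirical detection p-values (averaged over
#' resampling repeats of the negative-probeset null) and per-group P/M/A
#' calls.
#'
#' @slot pvalues numeric matrix probesets x arrays, values in (0, 1].
#' @slot calls character matrix probesets x groups with entries P/M/A.
#' @slot threshold numeric p-value threshold used for array-level presence.
#' @slot nRepeats integer number of resampling repeats averaged.
#' @export
setClass("DetectionResult",
    representation(pvalues = "matrix", calls = "matrix",
                   threshold = "numeric", nRepeats = "integer"))

setValidity("DetectionResult", function(object) {
    msg <- character()
    p <- object@pvalues
    if (any(p <= 0 | p > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
    if (!all(object@calls %in% c("P", "M", "A")))
        msg <- c(msg, "calls must be P, M or A")
    if (object@threshold <= 0 || object@threshold >= 1)
        msg <- c(msg, "threshold must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Genotyping counts from a reciprocal cross
#'
#' Progeny counts from a heterozygote x wild-type cross used for
#' transmission-efficiency and segregation chi-square statistics.
#'
#' @slot nHet,nWt non-negative integer progeny counts.
#' @slot direction `"female"` or `"male"` (which parent carried the allele).
#' @slot line free-text line label.
#' @export
setClass("CrossCounts",
    representation(nHet = "integer", nWt = "integer",
                   direction = "character", line = "character"))

setValidity("CrossCounts", function(object) {
    msg <- character()
    if (object@nHet < 0L || object@nWt < 0L)
        msg <- c(msg, "counts must be non-negative")
    if (object@nHet + object@nWt < 1L)
        msg <- c(msg, "at least one progeny is required")
    if (!object@direction %in% c("female", "male"))
        msg <- c(msg, "direction must be 'female' or 'male'")
    if (length(msg)) msg else TRUE
})

#' Gene Ontology graph with gene annotations
#'
#' A directed acyclic graph of terms (child -> parent links, is_a/part_of
#' collapsed) together with directly annotated genes per term and, after
#' [propagateAnnotations()], the true-path closure (each term inherits the
#' genes of all its descendants).
#'
#' @slot terms character vector of term ids.
#' @slot parents named list: term -> character vector of parent term ids.
#' @slot directAnnotation named list: term -> directly annotated genes.
#' @slot propagated named list or empty: term -> closed gene sets.
#' @export
setClass("GoDag",
    representation(terms = "character", parents = "list",
                   directAnnotation = "list", propagated = "list"))

setValidity("GoDag", function(object) {
    msg <- character()
    if (!all(names(object@parents) %in% object@terms) ||
        !all(unlist(object@parents) %in% object@terms))
        msg <- c(msg, "parent links must reference known terms")
    if (length(object@propagated) &&
        !all(names(object@propagated) %in% object@terms))
        msg <- c(msg, "propagated sets must be named by known terms")
    if (length(msg)) msg else TRUE
})
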