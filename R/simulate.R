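#' @include AllClasses.R
NULL

#' Create a simulation configuration
#'
#' Constructor for [SimulationConfig]. Defaults mirror a small ATH1-style
#' design: probesets of 11 perfect-match 25-mers, 4 replicates per tissue,
#' a Gaussian optical background plus an exponential expression signal on the
#' log2 scale, and probe-specific, array-invariant affinities.
#'
#' @param nGenes,nTissues numbers of genes and tissue groups.
#' @param probesPerSet probes per probeset (default 11).
#' @param replicatesPerTissue replicate arrays per tissue (default 4).
#' @param nNegativeProbes background-only probes to emit (default 100).
#' @param plantedEnriched data.frame (`gene`, `tissue`, `effect` in log2
#'   units) of planted tissue-enriched genes; may be empty.
#' @param backgroundMean,backgroundSd log2 background level and spread.
#' @param signalRate exponential rate of the expressed-signal component; the
#'   default 0.5 puts expressed genes on average 2 log2 units (4-fold)
#'   above background, keeping the simulated dynamic range inside the
#'   6-16 log2 window of real scanners.
#' @param affinitySd per-probe log2 affinity SD.
#' @param nMultimapProbes probes planted as exact substrings of two genes.
#' @param probeLength probe length in nt (default 25).
#' @param geneLength transcript length in nt (default 400).
#' @param pExpressed per-tissue expression probability for non-planted genes.
#' @param seed integer seed fixing all generator randomness.
#' @return a validated [SimulationConfig].
#' @export
#' @examples
#' simulationConfig(nGenes = 5, nTissues = 2, probesPerSet = 3, seed = 1)
simulationConfig <- function(nGenes, nTissues, probesPerSet = 11L,
        replicatesPerTissue = 4L, nNegativeProbes = 100L,
        plantedEnriched = data.frame(gene = character(),
            tissue = character(), effect = numeric()),
        backgroundMean = 6, backgroundSd = 1, signalRate = 0.5,
        affinitySd = 0.5, nMultimapProbes = 0L, probeLength = 25L,
        geneLength = 400L, pExpressed = 0.7, seed = 1L) {
    if (nMultimapProbes > floor(nGenes / 2))
        stop("nMultimapProbes must be at most nGenes/2")
    new("SimulationConfig", nGenes = as.integer(nGenes),
        probesPerSet = as.integer(probesPerSet),
        nTissues = as.integer(nTissues),
        replicatesPerTissue = as.integer(replicatesPerTissue),
        nNegativeProbes = as.integer(nNegativeProbes),
        plantedEnriched = plantedEnriched,
        backgroundMean = backgroundMean, backgroundSd = backgroundSd,
        signalRate = signalRate, affinitySd = affinitySd,
        nMultimapProbes = as.integer(nMultimapProbes),
        probeLength = as.integer(probeLength),
        geneLength = as.integer(geneLength), pExpressed = pExpressed,
        seed = as.integer(seed))
}

#' Canned atlas configuration used throughout examples and tests
#'
#' An 8-tissue x 4-replicate synthetic atlas of 500 genes with 20 genes
#' planted as enriched in the first tissue (the MMC-like target) at log2
#' effects evenly spaced from +2 to +4, 200 negative probes and 20
#' deliberately multi-mapping probes.
#'
#' @param seed integer seed.
#' @param nGenes,nTissues,nPlanted,nNegativeProbes,nMultimapProbes scale
#'   overrides for quick experiments.
#' @return a [SimulationConfig].
#' @export
mmcAtlasConfig <- function(seed = 1L, nGenes = 500L, nTissues = 8L,
                           nPlanted = 20L, nNegativeProbes = 200L,
                           nMultimapProbes = 20L) {
    genes <- sprintf("gene%04d", seq_len(nGenes))
    planted <- data.frame(
        gene = genes[seq_len(nPlanted)],
        tissue = rep(sprintf("tissue%02d", 1L), nPlanted),
        effect = seq(2, 4, length.out = nPlanted))
    simulationConfig(nGenes = nGenes, nTissues = nTissues,
        plantedEnriched = planted, nNegativeProbes = nNegativeProbes,
        nMultimapProbes = nMultimapProbes, seed = seed)
}

.geneIds <- function(config)
    sprintf("gene%04d", seq_len(config@nGenes))

.tissueNames <- function(config)
    sprintf("tissue%02d", seq_len(config@nTissues))

.geneProbeIds <- function(config) {
    genes <- .geneIds(config)
    as.vector(t(outer(genes, seq_len(config@probesPerSet),
                      function(g, i) sprintf("%s_p%02d", g, i))))
}

.negativeIds <- function(config)
    sprintf("neg%04d", seq_len(config@nNegativeProbes))

.randomDNA <- function(n, len)
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))

#' Generate synthetic gene, genome and probe sequences with ground truth
#'
#' Emits, fully determined by the configuration seed: transcript sequences;
#' a genome of one flanked contig per gene plus a decoy contig; probe
#' sequences (exact 25-mer substrings of their gene, evenly spaced, plus
#' random background-only negative probes); the declared probe-to-probeset
#' mapping table; and the [GroundTruth]. The configured number of
#' multi-mapping probes is planted by splicing one probe of a source gene
#' into the tail of a second gene, so that the probe is an exact substring of
#' both. Every negative probe is verified by a mismatch scan against all
#' targets (transcripts sense strand, genome both strands) before emission:
#' its best Hamming match must exceed 2 mismatches. Rejected candidates are
#' redrawn up to 1,000 rounds; exhaustion is an error.
#'
#' @param config a [SimulationConfig].
#' @return list with elements `genes`, `genome`, `probes`
#'   ([Biostrings::DNAStringSet]), `mapping` (data.frame `probe_id`,
#'   `probeset_id`, `gene_id`) and `truth` ([GroundTruth]).
#' @export
#' @examples
#' seqs <- generateSequences(
#'     simulationConfig(nGenes = 2, nTissues = 2, probesPerSet = 3,
#'                      nNegativeProbes = 4, seed = 7))
#' length(seqs$probes)  # 2 * 3 gene probes + 4 negatives
generateSequences <- function(config) {
    validObject(config)
    set.seed(config@seed)
    L <- config@geneLength
    w <- config@probeLength
    k <- config@probesPerSet
    genes <- .geneIds(config)

    ## probe starts confined to [1, L - w - 59]; the final 60 nt stay free
    ## for the multimap splice region
    lastStart <- L - w - 59L
    starts <- unique(round(seq(1L, lastStart, length.out = k)))
    if (length(starts) < k)
        stop("geneLength too short to place ", k, " distinct probes")

    geneSeq <- .randomDNA(config@nGenes, L)
    names(geneSeq) <- genes

    ## plant multimap probes: middle probe of source gene i spliced into the
    ## tail of gene (nGenes - i + 1); source/target sets are disjoint
    multimapIds <- character(0)
    if (config@nMultimapProbes > 0L) {
        mid <- ceiling(k / 2)
        ## source genes from the middle of the index range so that probe
        ## removal does not systematically hit the low-index genes tests
        ## like to plant effects on
        src <- config@nGenes %/% 2L - seq_len(config@nMultimapProbes) + 1L
        dst <- config@nGenes - src + 1L
        for (i in seq_along(src)) {
            pseq <- substr(geneSeq[src[i]], starts[mid], starts[mid] + w - 1L)
            substr(geneSeq[dst[i]], L - w + 1L, L) <- pseq
        }
        multimapIds <- sprintf("%s_p%02d", genes[src], mid)
    }

    probeSeq <- unlist(lapply(genes, function(g)
        vapply(starts, function(s)
            substr(geneSeq[[g]], s, s + w - 1L), character(1))))
    names(probeSeq) <- .geneProbeIds(config)

    flank <- .randomDNA(2L * config@nGenes, 50L)
    contig <- paste0(flank[seq_len(config@nGenes)], geneSeq,
                     flank[config@nGenes + seq_len(config@nGenes)])
    names(contig) <- paste0("chr_", genes)
    decoy <- .randomDNA(1L, 5000L)
    genome <- c(contig, decoy = decoy)
    targetGene <- c(stats::setNames(genes, names(contig)), decoy = NA)

    transcripts <- Biostrings::DNAStringSet(geneSeq)
    genomeSet <- Biostrings::DNAStringSet(genome)

    ## negative probes: rejection sampling with a mismatch-scan verification
    negSeq <- character(0)
    if (config@nNegativeProbes > 0L) {
        need <- config@nNegativeProbes
        kept <- character(0)
        for (round in seq_len(1000L)) {
            cand <- .randomDNA(need, w)
            cs <- Biostrings::DNAStringSet(cand)
            names(cs) <- sprintf("cand%d", seq_along(cs))
            bad <- unique(c(
                mapProbes(cs, transcripts, maxMismatches = 2L,
                          targetKind = "transcript")$probe_id,
                mapProbes(cs, genomeSet, maxMismatches = 2L,
                          targetKind = "genomic")$probe_id))
            kept <- c(kept, cand[!names(cs) %in% bad])
            need <- config@nNegativeProbes - length(kept)
            if (need == 0L) break
        }
        if (need > 0L)
            stop("failed to place ", need,
                 " negative probes within the retry cap")
        negSeq <- kept[seq_len(config@nNegativeProbes)]
        names(negSeq) <- .negativeIds(config)
    }

    probes <- Biostrings::DNAStringSet(c(probeSeq, negSeq))

    tissues <- .tissueNames(config)
    expressed <- matrix(stats::runif(config@nGenes * config@nTissues) <
                            config@pExpressed,
                        nrow = config@nGenes,
                        dimnames = list(genes, tissues))
    planted <- config@plantedEnriched
    if (nrow(planted)) {
        if (!all(planted$gene %in% genes) ||
            !all(planted$tissue %in% tissues))
            stop("plantedEnriched references unknown genes or tissues")
        expressed[planted$gene, ] <- TRUE
    }

    mapping <- data.frame(
        probe_id = names(probeSeq),
        probeset_id = paste0(rep(genes, each = k), "_at"),
        gene_id = rep(genes, each = k))

    truth <- new("GroundTruth", expressed = expressed,
                 enriched = planted,
                 negativeProbeIds = names(negSeq) %||% character(0),
                 multimapProbeIds = multimapIds,
                 targetGene = targetGene)
    list(genes = transcripts, genome = genomeSet, probes = probes,
         mapping = mapping, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate raw probe-level intensities
#'
#' Intensity model on the log2 scale: every probe on every array receives its
#' array-invariant affinity plus Gaussian optical background
#' `N(backgroundMean, backgroundSd)`. Probes of a gene expressed in an
#' array's tissue additionally receive the gene's expression level, drawn
#' once per gene from `Exp(signalRate)` and shared across tissues, plus the
#' planted log2 effect where (gene, tissue) is planted. Planted genes
#' receive the median baseline level instead of a random draw, so their
#' between-tissue contrast equals the planted effect by construction.
#' Values are then
#' exponentiated, so the raw-scale data approximately (not exactly) follow
#' the additive background + exponential signal convolution assumed by RMA.
#'
#' @param config the [SimulationConfig] that produced `truth`.
#' @param truth the [GroundTruth] from [generateSequences()].
#' @return a [ProbeIntensities] over all gene probes and negative probes,
#'   with `tissue` and `replicate` column metadata.
#' @export
simulateIntensities <- function(config, truth) {
    validObject(config); validObject(truth)
    genes <- .geneIds(config)
    tissues <- .tissueNames(config)
    if (!identical(rownames(truth@expressed), genes) ||
        !identical(colnames(truth@expressed), tissues))
        stop("truth is not consistent with config")
    set.seed(config@seed + 1L)

    probeIds <- c(.geneProbeIds(config), truth@negativeProbeIds)
    probeGene <- c(rep(genes, each = config@probesPerSet),
                   rep(NA_character_, length(truth@negativeProbeIds)))
    nProbes <- length(probeIds)

    arrTissue <- rep(tissues, each = config@replicatesPerTissue)
    arrRep <- rep(seq_len(config@replicatesPerTissue), config@nTissues)
    arrayIds <- sprintf("%s_r%d", arrTissue, arrRep)
    nArrays <- length(arrayIds)

    affinity <- stats::rnorm(nProbes, 0, config@affinitySd)
    level <- stats::rexp(config@nGenes, rate = config@signalRate)
    names(level) <- genes
    ## planted genes get the median baseline level: their tissue contrast
    ## is then determined by the planted effect, not by a random draw
    if (nrow(truth@enriched))
        level[unique(truth@enriched$gene)] <-
            stats::qexp(0.5, rate = config@signalRate)

    effect <- matrix(0, config@nGenes, config@nTissues,
                     dimnames = list(genes, tissues))
    if (nrow(truth@enriched))
        effect[cbind(truth@enriched$gene, truth@enriched$tissue)] <-
            truth@enriched$effect

    log2I <- matrix(stats::rnorm(nProbes * nArrays, config@backgroundMean,
                                 config@backgroundSd),
                    nrow = nProbes, dimnames = list(probeIds, arrayIds))
    log2I <- log2I + affinity
    geneRow <- !is.na(probeGene)
    for (a in seq_len(nArrays)) {
        t <- arrTissue[a]
        on <- truth@expressed[probeGene[geneRow], t]
        add <- ifelse(on, level[probeGene[geneRow]] +
                          effect[cbind(probeGene[geneRow], t)], 0)
        log2I[geneRow, a] <- log2I[geneRow, a] + add
    }

    probeIntensities(2^log2I,
        arrayInfo = data.frame(array_id = arrayIds, tissue = arrTissue,
                               replicate = arrRep, row.names = arrayIds))
}

#' Construct a ProbeIntensities container
#'
#' @param values positive probe x array matrix with row and column names.
#' @param arrayInfo data.frame with one row per array and columns `tissue`
#'   and `replicate`.
#' @return a [ProbeIntensities].
#' @export
probeIntensities <- function(values, arrayInfo) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = values),
        colData = S4Vectors::DataFrame(arrayInfo))
    new("ProbeIntensities", se)
}

#' Simulate progeny genotype counts from a reciprocal cross
#'
#' Progeny of a heterozygote x wild-type cross carry the mutant allele with
#' probability `p / (1 + p)` where `p` is the transmission probability of the
#' mutant gamete relative to the wild-type gamete; the heterozygous count is
#' binomial and the wild-type count is the remainder.
#'
#' @param nProgeny number of genotyped progeny (> 0).
#' @param transmissionProb relative transmission probability in `[0, 1]`
#'   (1 = Mendelian).
#' @param seed integer seed.
#' @param direction `"female"` or `"male"`.
#' @param line line label.
#' @return a [CrossCounts].
#' @export
#' @examples
#' simulateCross(150, 0.12, seed = 1)
simulateCross <- function(nProgeny, transmissionProb, seed = 1L,
                          direction = "female", line = "synthetic") {
    if (nProgeny <= 0L) stop("nProgeny must be > 0")
    if (transmissionProb < 0 || transmissionProb > 1)
        stop("transmissionProb must lie in [0, 1]")
    set.seed(as.integer(seed))
    p <- transmissionProb / (1 + transmissionProb)
    het <- stats::rbinom(1L, as.integer(nProgeny), p)
    crossCounts(het, as.integer(nProgeny) - het, direction = direction,
                line = line)
}

#' Write / read an intensity matrix as TSV with an array-metadata sidecar
#'
#' The matrix file has probes as rows (first column `probe_id`) and a header
#' of array ids; the sidecar has columns `array_id`, `tissue`, `replicate`.
#'
#' @param x a [ProbeIntensities].
#' @param file,sidecar paths of the matrix TSV and the metadata TSV.
#' @return `writeIntensityMatrix` returns `file` invisibly;
#'   `readIntensityMatrix` returns a [ProbeIntensities].
#' @export
writeIntensityMatrix <- function(x, file, sidecar) {
    m <- intensities(x)
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(arrayInfo(x)), sidecar, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeIntensityMatrix
#' @export
readIntensityMatrix <- function(file, sidecar) {
    df <- utils::read.delim(file, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
    info <- utils::read.delim(sidecar)
    rownames(info) <- info$array_id
    probeIntensities(m[, info$array_id, drop = FALSE], arrayInfo = info)
}
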