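#' @include AllClasses.R
NULL

.ACGT <- c("A", "C", "G", "T")

## Pigeonhole-seeded Hamming search on the plus strand of `targets`.
## Probes are split into maxMM + 1 contiguous exact seeds; any window within
## maxMM substitutions of a probe must contain at least one seed verbatim.
## Seed hits are found with an Aho-Corasick dictionary scan over the
## concatenated targets, then candidate windows are verified by exact
## character comparison (substitution-only distance, no indels).
.hammingHits <- function(probes, targets, maxMM) {
    w <- Biostrings::width(probes)[1]
    nSeeds <- maxMM + 1L
    bounds <- floor(seq(0L, w, length.out = nSeeds + 1L))
    if (any(diff(bounds) < 1L))
        stop("probe length too short for ", maxMM, " mismatches")

    spacer <- strrep("-", w + 5L)
    targChar <- as.character(targets)
    big <- paste(targChar, collapse = spacer)
    absStart <- cumsum(c(1L, nchar(targChar) + nchar(spacer)))
    absStart <- absStart[seq_along(targChar)]
    subject <- Biostrings::DNAString(big)

    probeChar <- as.matrix(probes)
    ok <- probeChar %in% .ACGT
    dim(ok) <- dim(probeChar)
    cleanProbe <- rowSums(!ok) == 0L

    pidx <- integer(0); cstart <- integer(0)
    for (s in seq_len(nSeeds)) {
        from <- bounds[s] + 1L; to <- bounds[s + 1L]
        seeds <- Biostrings::subseq(probes[cleanProbe], from, to)
        if (length(seeds)) {
            pd <- Biostrings::PDict(seeds)
            m <- Biostrings::matchPDict(pd, subject)
            st <- Biostrings::startIndex(m)
            n <- lengths(st)
            if (sum(n)) {
                pidx <- c(pidx, rep(which(cleanProbe), n))
                cstart <- c(cstart, unlist(st, use.names = FALSE) - bounds[s])
            }
        }
    }
    ## probes containing non-ACGT letters cannot seed an exact dictionary
    ## match; scan them naively (every letter outside ACGT mismatches all)
    if (any(!cleanProbe)) {
        bigChars <- strsplit(big, "")[[1]]
        L <- length(bigChars)
        for (p in which(!cleanProbe)) {
            mm <- integer(L - w + 1L)
            for (j in seq_len(w)) {
                tj <- bigChars[j:(L - w + j)]
                mm <- mm + (tj != probeChar[p, j] | !tj %in% .ACGT |
                            !ok[p, j])
            }
            hit <- which(mm <= maxMM)
            pidx <- c(pidx, rep(p, length(hit)))
            cstart <- c(cstart, hit)
        }
    }
    if (!length(pidx))
        return(data.frame(probe = integer(0), target = integer(0),
                          offset = integer(0), mismatches = integer(0)))

    keep <- cstart >= 1L
    cand <- unique(data.frame(probe = pidx[keep], cstart = cstart[keep]))
    tIdx <- findInterval(cand$cstart, absStart)
    local <- cand$cstart - absStart[tIdx] + 1L
    inside <- local >= 1L & local + w - 1L <= nchar(targChar)[tIdx]
    cand <- cand[inside, , drop = FALSE]
    tIdx <- tIdx[inside]; local <- local[inside]
    if (!nrow(cand))
        return(data.frame(probe = integer(0), target = integer(0),
                          offset = integer(0), mismatches = integer(0)))

    win <- substring(big, cand$cstart, cand$cstart + w - 1L)
    Wm <- matrix(unlist(strsplit(win, ""), use.names = FALSE),
                 ncol = w, byrow = TRUE)
    Pm <- probeChar[cand$probe, , drop = FALSE]
    okm <- ok[cand$probe, , drop = FALSE]
    mm <- rowSums(Wm != Pm | !(Wm %in% .ACGT) | !okm)
    keep <- mm <= maxMM
    data.frame(probe = cand$probe[keep], target = tIdx[keep],
               offset = local[keep] - 1L, mismatches = as.integer(mm[keep]))
}

#' Map probes to target sequences by substitution-only mismatch search
#'
#' Finds every window of every target within `maxMismatches` substitutions
#' of a probe (exact Hamming distance, no indels), using pigeonhole seeding:
#' each probe is split into `maxMismatches + 1` exact seeds located with a
#' dictionary scan, and candidate windows are verified exhaustively.
#' Transcript targets are searched on the sense strand only (probes are
#' designed against the mRNA); genomic targets are searched on both strands,
#' with reverse-strand hits found by matching the reverse-complemented probe
#' and reported with strand `"-"` at the forward-coordinate window.
#'
#' Coordinates are 0-based half-open: a hit covers
#' `[offset, offset + probe length)` on the target. Letters outside A/C/G/T
#' (in probe or window) mismatch everything and trigger a warning.
#'
#' @param probes [Biostrings::DNAStringSet] of uniform width (named).
#' @param targets [Biostrings::DNAStringSet] of target sequences (named).
#' @param maxMismatches maximum substitutions reported (cap 5).
#' @param targetKind `"transcript"` (sense strand only) or `"genomic"`
#'   (both strands).
#' @return data.frame with columns `probe_id`, `target_id`, `target_kind`,
#'   `offset`, `strand`, `mismatches`.
#' @export
#' @examples
#' t <- Biostrings::DNAStringSet(c(tx = "ACGTACGTACGTACGTACGTACGTACGT"))
#' p <- Biostrings::subseq(t, 3, 27); names(p) <- "probe1"
#' mapProbes(p, t, maxMismatches = 0, targetKind = "transcript")
mapProbes <- function(probes, targets, maxMismatches = 2L,
                      targetKind = c("transcript", "genomic")) {
    targetKind <- match.arg(targetKind)
    if (length(probes) == 0L) stop("empty probe set")
    if (length(targets) == 0L) stop("empty target set")
    w <- unique(Biostrings::width(probes))
    if (length(w) != 1L) stop("probes must have uniform length")
    maxMismatches <- as.integer(maxMismatches)
    if (maxMismatches < 0L || maxMismatches > 5L)
        stop("maxMismatches must lie in 0..5")
    if (is.null(names(probes)) || is.null(names(targets)))
        stop("probes and targets must be named")
    pc <- as.matrix(probes)
    if (any(!pc %in% .ACGT))
        warning("non-ACGT probe letters are treated as mismatch-to-everything")
    tc <- Biostrings::uniqueLetters(targets)
    if (any(!tc %in% .ACGT))
        warning("non-ACGT target letters are treated as mismatch-to-everything")

    plus <- .hammingHits(probes, targets, maxMismatches)
    plus$strand <- rep("+", nrow(plus))
    res <- plus
    if (targetKind == "genomic") {
        rc <- Biostrings::reverseComplement(targets)
        minus <- .hammingHits(probes, rc, maxMismatches)
        if (nrow(minus)) {
            minus$offset <- Biostrings::width(targets)[minus$target] -
                minus$offset - w
            minus$strand <- "-"
            res <- rbind(res, minus)
        }
    }
    out <- data.frame(
        probe_id = names(probes)[res$probe],
        target_id = names(targets)[res$target],
        target_kind = rep(targetKind, nrow(res)),
        offset = res$offset, strand = res$strand,
        mismatches = res$mismatches)
    out[order(match(out$probe_id, names(probes)), out$target_id,
              out$offset), , drop = FALSE]
}

#' Build the probeset annotation, removing perfect multi-mappers
#'
#' Probes whose perfect (0-mismatch) hits cover more than one distinct gene
#' are removed from the declared probe-to-probeset mapping; probesets left
#' with fewer than `minProbes` probes are dropped and recorded. The
#' probeset-to-gene assignment comes from the mapping's `gene_id` column
#' when present, otherwise it is derived from the retained probes' perfect
#' transcript hits; a probeset resolving to two genes is an error.
#'
#' @param hits data.frame from [mapProbes()] (transcript and/or genomic
#'   hits, computed with `maxMismatches >= 0`).
#' @param mapping data.frame with columns `probe_id`, `probeset_id` and
#'   optionally `gene_id`.
#' @param minProbes minimum retained probes per probeset (default 1).
#' @param targetGene optional named character vector translating target ids
#'   to gene ids (genomic contigs, re-annotated transcript names); targets
#'   absent from it keep their own id when transcripts, and are ignored for
#'   multimap detection when genomic.
#' @return a [ProbesetAnnotation].
#' @export
buildProbesetAnnotation <- function(hits, mapping, minProbes = 1L,
                                    targetGene = NULL) {
    stopifnot(all(c("probe_id", "probeset_id") %in% names(mapping)))
    hitGene <- hits$target_id
    if (!is.null(targetGene)) {
        known <- hits$target_id %in% names(targetGene)
        hitGene[known] <- targetGene[hits$target_id[known]]
        hitGene[!known & hits$target_kind == "genomic"] <- NA
    } else {
        hitGene[hits$target_kind == "genomic"] <- NA
    }
    perfect <- hits$mismatches == 0L & !is.na(hitGene)
    genesPerProbe <- tapply(hitGene[perfect], hits$probe_id[perfect],
                            function(g) length(unique(g)))
    multi <- names(genesPerProbe)[genesPerProbe > 1L]

    removedIds <- intersect(mapping$probe_id, multi)
    removedProbes <- data.frame(
        probe_id = removedIds,
        reason = rep("multimap", length(removedIds)))
    keep <- !mapping$probe_id %in% multi
    kept <- mapping[keep, , drop = FALSE]

    probesetProbes <- split(kept$probe_id, kept$probeset_id)
    small <- lengths(probesetProbes) < minProbes
    removedProbesets <- sort(unique(c(
        setdiff(mapping$probeset_id, names(probesetProbes)),
        names(probesetProbes)[small])))
    probesetProbes <- probesetProbes[!small]

    if ("gene_id" %in% names(mapping)) {
        pg <- unique(kept[, c("probeset_id", "gene_id")])
        if (anyDuplicated(pg$probeset_id))
            stop("probeset mapped to two genes: ",
                 paste(pg$probeset_id[duplicated(pg$probeset_id)],
                       collapse = ", "))
        probesetGene <- stats::setNames(pg$gene_id, pg$probeset_id)
        probesetGene <- probesetGene[names(probesetProbes)]
    } else {
        tx <- hits$target_kind == "transcript" & perfect
        byProbe <- split(hitGene[tx], hits$probe_id[tx])
        probesetGene <- vapply(names(probesetProbes), function(ps) {
            g <- unique(unlist(byProbe[probesetProbes[[ps]]]))
            if (length(g) > 1L)
                stop("probeset mapped to two genes: ", ps)
            if (length(g)) g else NA_character_
        }, character(1))
    }
    new("ProbesetAnnotation",
        probesetGene = probesetGene,
        probesetProbes = probesetProbes[names(probesetGene)],
        removedProbes = removedProbes,
        removedProbesets = removedProbesets)
}

#' Select background-only negative probes
#'
#' The pool consists of probes that are not used by any retained probeset
#' and whose best hit over all targets and strands has more than two
#' mismatches -- or that have no hit at all at the search cap (included,
#' with `NA` provenance). Probes with any hit at two or fewer mismatches
#' measure signal, not background, and are excluded.
#'
#' @param probeIds character vector of all probe ids on the array, in order.
#' @param hits data.frame from [mapProbes()], computed with
#'   `maxMismatches >= 2`.
#' @param annotation a [ProbesetAnnotation]; its retained probes are
#'   excluded from the pool.
#' @return a [NegativeProbePool]; an empty pool is an error, because
#'   detection calling would be impossible.
#' @export
selectNegativeProbes <- function(probeIds, hits, annotation) {
    used <- unlist(annotation@probesetProbes, use.names = FALSE)
    best <- tapply(hits$mismatches, hits$probe_id, min)
    bestAll <- stats::setNames(rep(NA_integer_, length(probeIds)), probeIds)
    found <- intersect(probeIds, names(best))
    bestAll[found] <- as.integer(best[found])
    pool <- probeIds[!probeIds %in% used &
                     (is.na(bestAll) | bestAll > 2L)]
    if (!length(pool))
        stop("negative-probe pool is empty; detection calling impossible")
    new("NegativeProbePool", probeIds = pool,
        bestHitMismatches = bestAll[pool])
}

#' Write / read probe hits as TSV
#'
#' @param hits data.frame from [mapProbes()].
#' @param file path.
#' @return `writeProbeHits` returns `file` invisibly; `readProbeHits` the
#'   hits data.frame.
#' @export
writeProbeHits <- function(hits, file) {
    utils::write.table(hits, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeProbeHits
#' @export
readProbeHits <- function(file) utils::read.delim(file)
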