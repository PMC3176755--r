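# Independent brute-force oracles used to verify the package's fast paths.
# These deliberately avoid the implementation's algorithms (dictionary
# seeding, Lance-Williams updates, vectorized rank counting, ...) and use
# direct enumeration instead.

# All-window Hamming scan of one probe against one target (plus strand).
# Returns 0-based offsets and mismatch counts for every window within maxMM.
oracleHammingScan <- function(probe, target, maxMM) {
    p <- strsplit(probe, "")[[1]]
    t <- strsplit(target, "")[[1]]
    w <- length(p)
    acgt <- c("A", "C", "G", "T")
    out <- NULL
    for (o in seq_len(length(t) - w + 1L)) {
        win <- t[o:(o + w - 1L)]
        mm <- sum(win != p | !win %in% acgt | !p %in% acgt)
        if (mm <= maxMM)
            out <- rbind(out, data.frame(offset = o - 1L, mismatches = mm))
    }
    out
}

# Reverse complement of a plain character DNA string.
oracleRevComp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    x <- rev(strsplit(s, "")[[1]])
    paste(ifelse(x %in% names(comp), comp[x], x), collapse = "")
}

# Full mapping oracle over named character vectors of probes and targets.
oracleMapProbes <- function(probes, targets, maxMM, kind) {
    out <- NULL
    for (pn in names(probes)) {
        for (tn in names(targets)) {
            h <- oracleHammingScan(probes[[pn]], targets[[tn]], maxMM)
            if (!is.null(h) && nrow(h))
                out <- rbind(out, data.frame(probe_id = pn, target_id = tn,
                                             strand = "+", h))
            if (kind == "genomic") {
                w <- nchar(probes[[pn]])
                hr <- oracleHammingScan(oracleRevComp(probes[[pn]]),
                                        targets[[tn]], maxMM)
                if (!is.null(hr) && nrow(hr))
                    out <- rbind(out,
                        data.frame(probe_id = pn, target_id = tn,
                                   strand = "-", hr))
            }
        }
    }
    out
}

# Step-up BH adjustment, written from the definition.
oracleStepUpBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (k in m:1) {
        prev <- min(prev, m * p[o[k]] / k)
        adj[o[k]] <- prev
    }
    pmin(adj, 1)
}

# Complete-linkage clustering by recomputing every inter-cluster distance
# from the original matrix at each step (no Lance-Williams update). Returns
# the merge heights and the cophenetic distance matrix, which together
# determine the dendrogram.
oracleCompleteLinkage <- function(dm) {
    n <- nrow(dm)
    clusters <- as.list(seq_len(n))
    coph <- matrix(0, n, n)
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        k <- length(clusters)
        best <- c(Inf, NA, NA)
        for (i in seq_len(k - 1L)) {
            for (j in (i + 1L):k) {
                h <- max(dm[clusters[[i]], clusters[[j]]])
                if (h < best[1]) best <- c(h, i, j)
            }
        }
        i <- best[2]; j <- best[3]
        coph[clusters[[i]], clusters[[j]]] <- best[1]
        coph[clusters[[j]], clusters[[i]]] <- best[1]
        heights <- c(heights, best[1])
        clusters[[i]] <- c(clusters[[i]], clusters[[j]])
        clusters[[j]] <- NULL
    }
    list(heights = heights, cophenetic = coph)
}

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins: sum point probabilities not exceeding the observed one.
oracleFisherTwoSided <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0L, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    obs <- dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# Transitive closure of a child->parent relation by boolean matrix powers.
oracleClosure <- function(terms, childParent) {
    n <- length(terms)
    A <- matrix(FALSE, n, n, dimnames = list(terms, terms))
    for (i in seq_len(nrow(childParent)))
        A[childParent$child[i], childParent$parent[i]] <- TRUE
    R <- A
    for (step in seq_len(n)) R <- R | (R %*% A > 0)
    R
}

# Small synthetic dataset shared across annotation/detection tests.
smallSyntheticData <- function(seed = 42L, nGenes = 8L, nTissues = 3L,
                               probesPerSet = 4L, nNegativeProbes = 20L,
                               nMultimapProbes = 2L, ...) {
    cfg <- simulationConfig(nGenes = nGenes, nTissues = nTissues,
        probesPerSet = probesPerSet, nNegativeProbes = nNegativeProbes,
        nMultimapProbes = nMultimapProbes, seed = seed, ...)
    seqs <- generateSequences(cfg)
    list(cfg = cfg, seqs = seqs,
         intensities = simulateIntensities(cfg, seqs$truth))
}

# Probeset annotation taken directly from the generator's declared mapping
# (used where a test exercises downstream stages, not the mapping search).
annotationFromMapping <- function(mapping) {
    sets <- split(mapping$probe_id, mapping$probeset_id)
    genes <- vapply(split(mapping$gene_id, mapping$probeset_id),
                    function(g) unique(g), character(1))
    methods::new("ProbesetAnnotation", probesetGene = genes[names(sets)],
        probesetProbes = sets,
        removedProbes = data.frame(probe_id = character(0),
                                   reason = character(0)),
        removedProbesets = character(0))
}
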