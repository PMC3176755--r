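mkDNA <- function(x) Biostrings::DNAStringSet(x)

test_that("exact, mismatched and reverse-strand hits are reported correctly", {
    set.seed(1)
    tx <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    targets <- mkDNA(c(tx1 = tx))
    probe <- substr(tx, 31, 55)
    p <- mkDNA(c(p1 = probe))

    h <- mapProbes(p, targets, maxMismatches = 0,
                   targetKind = "transcript")
    expect_equal(nrow(h), 1)
    expect_equal(h$offset, 30)      # 0-based
    expect_equal(h$mismatches, 0)
    expect_equal(h$strand, "+")

    # three substitutions, cap two: no hits
    mut <- probe
    substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
    substr(mut, 12, 12) <- if (substr(mut, 12, 12) == "G") "T" else "G"
    substr(mut, 22, 22) <- if (substr(mut, 22, 22) == "A") "G" else "A"
    h3 <- mapProbes(mkDNA(c(pm = mut)), targets, maxMismatches = 2,
                    targetKind = "transcript")
    expect_equal(nrow(h3), 0)

    # reverse complement of a genomic window: strand "-", forward offset
    rcp <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(probe)))
    hrc <- mapProbes(mkDNA(c(pr = rcp)), targets, maxMismatches = 0,
                     targetKind = "genomic")
    expect_equal(hrc$strand, "-")
    expect_equal(hrc$offset, 30)
    # and transcripts are sense-strand only
    expect_equal(nrow(mapProbes(mkDNA(c(pr = rcp)), targets,
                                maxMismatches = 0,
                                targetKind = "transcript")), 0)
})

test_that("seeded search agrees exactly with the naive Hamming oracle", {
    set.seed(8)
    targets <- c(t1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                            collapse = ""),
                 t2 = paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                            collapse = ""))
    # probes: corrupted substrings (0-3 substitutions) plus random 25-mers
    probes <- character(0)
    for (i in 1:8) {
        src <- targets[[1 + i %% 2]]
        o <- sample(nchar(src) - 24, 1)
        p <- substr(src, o, o + 24)
        nmut <- i %% 4
        if (nmut > 0)
            for (j in sample(25, nmut)) {
                old <- substr(p, j, j)
                substr(p, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                                  old), 1)
            }
        probes <- c(probes, p)
    }
    probes <- c(probes, vapply(1:4, function(i)
        paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""),
        character(1)))
    names(probes) <- sprintf("p%02d", seq_along(probes))

    for (kind in c("transcript", "genomic")) {
        got <- mapProbes(mkDNA(probes), mkDNA(targets), maxMismatches = 2,
                         targetKind = kind)
        # the oracle scans the reverse-complemented probe against the
        # forward target, so its "-" offsets are already forward-window
        # starts, the same convention mapProbes reports
        want <- oracleMapProbes(probes, targets, maxMM = 2, kind = kind)
        key <- function(d) sort(paste(d$probe_id, d$target_id, d$offset,
                                      d$strand, d$mismatches))
        expect_identical(key(got),
                         if (is.null(want)) character(0) else key(want))
    }
})

test_that("input contracts of the mapper are enforced", {
    t <- mkDNA(c(t1 = "ACGTACGTACGTACGTACGTACGTACGTACGT"))
    expect_error(mapProbes(mkDNA(character(0)), t), "empty probe")
    expect_error(mapProbes(t, mkDNA(character(0))), "empty target")
    expect_error(mapProbes(mkDNA(c(a = "ACGT", b = "ACGTA")), t),
                 "uniform")
    expect_warning(
        mapProbes(mkDNA(c(p = "ACGTNACGTACGTACGTACGTACGT")), t,
                  maxMismatches = 2, targetKind = "transcript"),
        "non-ACGT")
})

test_that("perfect multi-mappers are removed and empty probesets dropped", {
    hits <- data.frame(
        probe_id = c("pA1", "pA1", "pA2", "pB1", "pB2", "pC1"),
        target_id = c("geneA", "geneB", "geneA", "geneB", "geneB",
                      "geneC"),
        target_kind = "transcript", offset = 0L, strand = "+",
        mismatches = c(0L, 0L, 0L, 0L, 0L, 0L))
    mapping <- data.frame(
        probe_id = c("pA1", "pA2", "pB1", "pB2", "pC1"),
        probeset_id = c("psA", "psA", "psB", "psB", "psC"),
        gene_id = c("geneA", "geneA", "geneB", "geneB", "geneC"))

    ann <- buildProbesetAnnotation(hits, mapping)
    expect_equal(ann@removedProbes$probe_id, "pA1")
    expect_equal(ann@removedProbes$reason, "multimap")
    expect_setequal(ann@probesetProbes$psA, "pA2")

    # a probeset whose probes are all multimapping disappears
    hits2 <- rbind(hits,
        data.frame(probe_id = "pC1", target_id = "geneA",
                   target_kind = "transcript", offset = 5L, strand = "+",
                   mismatches = 0L))
    ann2 <- buildProbesetAnnotation(hits2, mapping, minProbes = 1)
    expect_true("psC" %in% ann2@removedProbesets)
    expect_false("psC" %in% names(ann2@probesetProbes))

    # hand enumeration: surviving probe counts
    expect_equal(lengths(ann2@probesetProbes)[c("psA", "psB")],
                 c(psA = 1L, psB = 2L))

    # removing multimappers is idempotent
    kept <- mapping[mapping$probe_id %in%
                    unlist(ann2@probesetProbes), , drop = FALSE]
    ann3 <- buildProbesetAnnotation(hits2, kept, minProbes = 1)
    expect_identical(ann3@probesetProbes, ann2@probesetProbes)
    expect_equal(nrow(ann3@removedProbes), 0)
})

test_that("a probeset mapped to two genes is an error", {
    hits <- data.frame(probe_id = "p1", target_id = "geneA",
                       target_kind = "transcript", offset = 0L,
                       strand = "+", mismatches = 0L)
    mapping <- data.frame(probe_id = c("p1", "p2"),
                          probeset_id = c("ps1", "ps1"),
                          gene_id = c("geneA", "geneB"))
    expect_error(buildProbesetAnnotation(hits, mapping), "two genes")
})

test_that("negative-probe selection applies the >2 mismatch rule", {
    hits <- data.frame(
        probe_id = c("used1", "close2", "far4"),
        target_id = "geneA", target_kind = "transcript", offset = 0L,
        strand = "+",
        mismatches = c(0L, 2L, 4L))
    ann <- annotationFromMapping(data.frame(
        probe_id = "used1", probeset_id = "psA", gene_id = "geneA"))
    pool <- selectNegativeProbes(c("used1", "close2", "far4", "nohit"),
                                 hits, ann)
    expect_setequal(negativeProbeIds(pool), c("far4", "nohit"))
    expect_equal(pool@bestHitMismatches[["far4"]], 4L)
    expect_true(is.na(pool@bestHitMismatches[["nohit"]]))

    expect_error(selectNegativeProbes(c("used1", "close2"), hits, ann),
                 "empty")
})

test_that("on synthetic data the generator's negative pool is recovered exactly", {
    dat <- smallSyntheticData(seed = 13, nGenes = 10, nNegativeProbes = 15,
                              nMultimapProbes = 3)
    seqs <- dat$seqs
    hits <- rbind(
        mapProbes(seqs$probes, seqs$genes, 2, "transcript"),
        mapProbes(seqs$probes, seqs$genome, 2, "genomic"))
    ann <- buildProbesetAnnotation(hits, seqs$mapping,
                                   targetGene = seqs$truth@targetGene)
    # the planted multimappers (and only they) are removed
    expect_setequal(ann@removedProbes$probe_id,
                    seqs$truth@multimapProbeIds)
    pool <- selectNegativeProbes(names(seqs$probes), hits, ann)
    expect_setequal(negativeProbeIds(pool), seqs$truth@negativeProbeIds)
})
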