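test_that("pseudo-probeset resampling is uniform, exhaustive and deterministic", {
    pool <- sprintf("n%02d", 1:11)
    forced <- sampleNegativeProbesets(pool, setSize = 11, nSets = 1,
                                      nRepeats = 1, seed = 3)
    expect_setequal(forced[[1]][1, ], pool)

    a <- sampleNegativeProbesets(pool, setSize = 4, nSets = 10,
                                 nRepeats = 3, seed = 9)
    b <- sampleNegativeProbesets(pool, setSize = 4, nSets = 10,
                                 nRepeats = 3, seed = 9)
    expect_identical(a, b)
    # distinct probes within every set
    expect_true(all(vapply(a, function(m)
        all(apply(m, 1, anyDuplicated) == 0), logical(1))))

    expect_error(sampleNegativeProbesets(pool, setSize = 12), "smaller")

    # inclusion frequency ~ Binomial(nSets, setSize/poolSize)
    pool100 <- sprintf("n%03d", 1:100)
    s <- sampleNegativeProbesets(pool100, setSize = 11, nSets = 10000,
                                 nRepeats = 1, seed = 1)[[1]]
    freq <- table(factor(as.vector(s), levels = pool100)) / nrow(s)
    se <- sqrt(0.11 * 0.89 / nrow(s))
    expect_true(all(abs(freq - 0.11) <= 3 * se + 1e-12))
})

test_that("null signals use the shared RMA path and are reproducible", {
    set.seed(4)
    l2 <- matrix(rnorm(40 * 3), 40,
                 dimnames = list(sprintf("n%02d", 1:40),
                                 paste0("a", 1:3)))
    s <- sampleNegativeProbesets(rownames(l2), setSize = 5, nSets = 120,
                                 nRepeats = 2, seed = 5)
    ns <- nullSignals(s, l2)
    expect_length(ns, 2)
    expect_true(all(vapply(ns, function(m) all(is.finite(m)),
                           logical(1))))
    # identical to summarizing each pseudo-probeset as a real probeset
    i <- 7
    expect_equal(ns[[1]][i, ],
                 medianPolish(l2[s[[1]][i, ], ])$expression)
    expect_identical(ns, nullSignals(s, l2))
    expect_warning(nullSignals(s, l2, method = "mas5"), "RMA path")

    # single-array shortcut equals the general path
    s1 <- lapply(s, identity)
    one <- l2[, 1, drop = FALSE]
    direct <- vapply(seq_len(nrow(s1[[1]])), function(i)
        medianPolish(one[s1[[1]][i, ], , drop = FALSE])$expression,
        numeric(1))
    expect_equal(nullSignals(s1, one)[[1]][, 1], direct,
                 ignore_attr = TRUE)
})

test_that("detection p-values equal the direct rank-counting oracle", {
    set.seed(6)
    nulls <- lapply(1:3, function(r)
        matrix(rnorm(150 * 2), 150,
               dimnames = list(NULL, c("a1", "a2"))))
    x <- matrix(c(-5, 0.3, 5, 0, 1.2, -1),
                nrow = 3, dimnames = list(paste0("g", 1:3),
                                          c("a1", "a2")))
    p <- detectionPValues(x, nulls)
    for (g in 1:3) for (a in 1:2) {
        oracle <- mean(vapply(nulls, function(nm)
            (sum(nm[, a] >= x[g, a]) + 1) / (nrow(nm) + 1), numeric(1)))
        expect_equal(p[g, a], oracle)
    }
    # boundaries
    expect_equal(p["g3", "a1"], 1 / 151)   # above all null signals
    expect_equal(p["g1", "a1"], 1)         # below all null signals

    bad <- lapply(nulls, function(m) {
        colnames(m) <- c("a1", "zz"); m })
    expect_error(detectionPValues(x, bad), "mismatch")
    expect_error(detectionPValues(x, lapply(nulls, function(m) m[1:50, ])),
                 "100 null sets")
})

test_that("present/marginal/absent calls follow the replicate rules", {
    p <- rbind(
        g1 = c(0.01, 0.015, 0.019, 0.5),  # 3/4 present -> P
        g2 = c(0.01, 0.01, 0.5, 0.5),     # 2/4 present -> M
        g3 = c(0.5, 0.5, 0.5, 0.5),       # absent
        g4 = c(0.02, 0.02, 0.02, 0.02))   # threshold inclusive -> P
    calls <- callPresence(p, groups = rep("MMC", 4))
    expect_equal(calls[, "MMC"],
                 c(g1 = "P", g2 = "M", g3 = "A", g4 = "P"))

    # categories partition the probesets (disjoint and exhaustive)
    set.seed(7)
    pr <- matrix(runif(600), 100,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
    cl <- callPresence(pr, groups = rep(c("x", "y"), each = 3))
    expect_true(all(cl %in% c("P", "M", "A")))

    expect_error(callPresence(p, rep("MMC", 4), threshold = 1.2),
                 "threshold")
    expect_error(callPresence(p, c("a", "a", "a", "b")), "2 arrays")
})

test_that("presence fractions generalize by ceiling to other replicate counts", {
    p <- rbind(g1 = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.5))
    # R = 6: present needs ceiling(4.5) = 5, marginal ceiling(3) = 3
    expect_equal(unname(callPresence(p, rep("g", 6))[1, 1]), "M")
    p2 <- rbind(g1 = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.5))
    expect_equal(unname(callPresence(p2, rep("g", 6))[1, 1]), "P")
})

test_that("detection p-values are calibrated under the null", {
    set.seed(10)
    poolIds <- sprintf("n%03d", 1:500)
    l2 <- matrix(rnorm(500), ncol = 1,
                 dimnames = list(poolIds, "a1"))
    s <- sampleNegativeProbesets(poolIds, setSize = 11, nSets = 500,
                                 nRepeats = 5, seed = 11)
    null <- nullSignals(s, l2)
    test <- matrix(apply(matrix(rnorm(4000 * 11), ncol = 11), 1, median),
                   ncol = 1, dimnames = list(NULL, "a1"))
    p <- detectionPValues(test, null)
    for (t in c(0.01, 0.02, 0.05)) {
        se <- sqrt(t * (1 - t) / nrow(test))
        # allow for the pool's own sampling error on top of the binomial
        # Monte-Carlo error (finite pool of 500 values)
        expect_lt(abs(mean(p <= t) - t), 3 * se + 0.015)
    }
})

test_that("averaging over repeats reduces the p-value spread", {
    set.seed(12)
    poolIds <- sprintf("n%03d", 1:300)
    l2 <- matrix(rnorm(300), ncol = 1, dimnames = list(poolIds, "a1"))
    x <- matrix(0.45, 1, 1, dimnames = list("g1", "a1"))
    pAt <- function(nRep, seed) {
        s <- sampleNegativeProbesets(poolIds, setSize = 11, nSets = 200,
                                     nRepeats = nRep, seed = seed)
        detectionPValues(x, nullSignals(s, l2))[1, 1]
    }
    sd1 <- sd(vapply(1:12, function(s) pAt(1, s), numeric(1)))
    sd20 <- sd(vapply(1:12, function(s) pAt(20, s), numeric(1)))
    expect_lt(sd20, sd1)
    expect_lt(sd20, sd1 / 2)  # roughly follows the sqrt-law
})

test_that("venn region counts follow set algebra", {
    expect_equal(vennRegions(list(A = c("a", "b"),
                                  B = c("c", "d")))["A&B", "count"], 0)
    same <- vennRegions(list(A = c("a", "b"), B = c("a", "b")))
    expect_equal(same["A&B", "count"], 2)
    expect_equal(sum(same$count), 2)

    set.seed(13)
    uni <- sprintf("g%03d", 1:60)
    sets <- list(x = sample(uni, 25), y = sample(uni, 30),
                 z = sample(uni, 10))
    v <- vennRegions(sets)
    expect_equal(sum(v$count), length(unique(unlist(sets))))
    # spot-check two regions against direct set operations
    expect_equal(v["x&y&z", "count"],
                 length(Reduce(intersect, sets)))
    expect_equal(v["x", "count"],
                 length(setdiff(sets$x, union(sets$y, sets$z))))
})

test_that("the full detection pipeline separates planted signal from background", {
    # planted genes carry a strong +4 log2 signal in tissue01; everything
    # else is background-only (pExpressed = 0 silences non-planted genes
    # outside the planted set, which is forced on everywhere)
    planted <- data.frame(gene = sprintf("gene%04d", 1:5),
                          tissue = "tissue01", effect = 4)
    cfg <- simulationConfig(nGenes = 30, nTissues = 2, pExpressed = 0,
                            plantedEnriched = planted,
                            nNegativeProbes = 60, seed = 17)
    seqs <- generateSequences(cfg)
    pim <- simulateIntensities(cfg, seqs$truth)
    ann <- annotationFromMapping(seqs$mapping)
    pool <- methods::new("NegativeProbePool",
        probeIds = seqs$truth@negativeProbeIds,
        bestHitMismatches = stats::setNames(
            rep(NA_integer_, length(seqs$truth@negativeProbeIds)),
            seqs$truth@negativeProbeIds))
    det <- detectAboveBackground(pim, ann, pool, nSets = 300,
                                 nRepeats = 5, seed = 18)
    expect_s4_class(det, "DetectionResult")
    calls <- presenceCalls(det)
    ids <- paste0(planted$gene, "_at")
    expect_true(all(calls[ids, "tissue01"] == "P"))
    # background-only genes are overwhelmingly not called present
    offIds <- setdiff(rownames(calls), ids)
    expect_gt(mean(calls[offIds, ] == "A"), 0.9)
})
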