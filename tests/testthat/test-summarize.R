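test_that("background correction matches the conditional-expectation quadrature", {
    mu <- 50; sigma <- 20; alpha <- 1 / 200
    o <- c(60, 120, 300, 800, 2000)
    got <- backgroundCorrect(matrix(o, ncol = 1),
                             params = c(mu, sigma, alpha))[, 1]
    # quadrature oracle for E[S | O = o] under O = S + B
    oracle <- vapply(o, function(oo) {
        f <- function(s) stats::dnorm(oo - s, mu, sigma) *
            alpha * exp(-alpha * s)
        hi <- oo + 10 * sigma
        stats::integrate(function(s) s * f(s), 0, hi,
                         rel.tol = 1e-10)$value /
            stats::integrate(f, 0, hi, rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("background correction is monotone, positive, and has the sigma->0 limit", {
    set.seed(1)
    x <- sort(2^rnorm(500, 8, 1.5))
    bc <- backgroundCorrect(matrix(x, ncol = 1))[, 1]
    expect_true(all(diff(bc) > 0))
    expect_true(all(bc > 0))

    # sigma -> 0 with o >> mu: corrected ~ o - mu
    o <- c(1000, 5000)
    got <- backgroundCorrect(matrix(o, ncol = 1),
                             params = c(100, 1e-4, 1e-9))[, 1]
    expect_equal(got, o - 100, tolerance = 1e-3)

    expect_error(backgroundCorrect(matrix(rep(3, 10), ncol = 1)),
                 "degenerate")
})

test_that("quantile normalization equalizes columns with correct tie handling", {
    m <- cbind(a = c(1, 3, 5), b = c(8, 2, 4))
    got <- quantileNormalize(m)
    expect_equal(got[, "a"], c(1.5, 3.5, 6.5), ignore_attr = TRUE)
    expect_equal(sort(got[, "b"]), c(1.5, 3.5, 6.5), ignore_attr = TRUE)
    expect_equal(rank(got[, "b"]), rank(m[, "b"]))

    # idempotent; identical columns are a fixed point; single array unchanged
    expect_equal(quantileNormalize(got), got)
    same <- cbind(x = c(2, 7, 1), y = c(2, 7, 1))
    expect_equal(quantileNormalize(same), same)
    one <- matrix(c(4, 1, 9), dimnames = list(NULL, "only"))
    expect_equal(quantileNormalize(one), one)
})

test_that("median polish matches an independent sweep oracle", {
    # exactly additive matrix: residuals vanish after one sweep pair
    r <- c(1, 4, -2); cc <- c(0, 2, 5, 1)
    add <- outer(r, cc, `+`) + 3
    mp <- medianPolish(add)
    expect_equal(max(abs(mp$residuals)), 0)
    expect_true(mp$converged)
    expect_equal(outer(mp$probeEffects, mp$arrayEffects, `+`) + mp$overall,
                 add, ignore_attr = TRUE)

    # block with an outlier cell: agree with stats::medpolish run to
    # convergence (independent iterative implementation, same sweep order)
    set.seed(2)
    x <- matrix(rnorm(9), 3); x[2, 3] <- 7
    mine <- medianPolish(x, tol = 1e-10, maxIter = 200)
    ref <- stats::medpolish(x, eps = 1e-10, maxiter = 200,
                            trace.iter = FALSE)
    expect_equal(mine$overall, ref$overall, tolerance = 1e-8)
    expect_equal(unname(mine$arrayEffects), unname(ref$col),
                 tolerance = 1e-8)
    expect_equal(unname(mine$probeEffects), unname(ref$row),
                 tolerance = 1e-8)

    # degenerate single-probe block
    one <- matrix(c(5, 7, 6), 1)
    mp1 <- medianPolish(one)
    expect_equal(unname(mp1$expression), c(5, 7, 6))
    expect_equal(unname(mp1$probeEffects), 0)

    expect_error(medianPolish(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("rma output has probeset dimensions and is probe-order invariant", {
    dat <- smallSyntheticData(seed = 11, nGenes = 6, nNegativeProbes = 10)
    ann <- annotationFromMapping(dat$seqs$mapping)
    ex <- rmaSummarize(dat$intensities, ann)
    expect_s4_class(ex, "ProbesetExpression")
    expect_equal(dim(exprValues(ex)),
                 c(length(ann@probesetProbes), ncol(dat$intensities)))
    expect_equal(exprMethod(ex), "rma")

    perm <- sample(nrow(dat$intensities))
    pim2 <- probeIntensities(intensities(dat$intensities)[perm, ],
                             as.data.frame(arrayInfo(dat$intensities)))
    ex2 <- rmaSummarize(pim2, ann)
    expect_equal(exprValues(ex2), exprValues(ex))

    bad <- annotationFromMapping(data.frame(probe_id = "ghost",
        probeset_id = "psX", gene_id = "geneX"))
    expect_error(rmaSummarize(dat$intensities, bad), "ghost")
})

test_that("rma recovers a planted +4 log2 effect", {
    # the gene is planted well above background in both tissues (+6 vs
    # +2), so the contrast of 4 is measured away from the background-
    # correction nonlinearity and the sparse top quantiles
    planted <- data.frame(gene = "gene0005",
                          tissue = c("tissue01", "tissue02"),
                          effect = c(6, 2))
    cfg <- simulationConfig(nGenes = 300, nTissues = 2, pExpressed = 1,
                            replicatesPerTissue = 8,
                            plantedEnriched = planted,
                            nNegativeProbes = 60, seed = 3)
    seqs <- generateSequences(cfg)
    pim <- simulateIntensities(cfg, seqs$truth)
    ann <- annotationFromMapping(seqs$mapping)
    e <- exprValues(rmaSummarize(pim, ann))
    ti <- arrayInfo(pim)$tissue
    est <- mean(e["gene0005_at", ti == "tissue01"]) -
        mean(e["gene0005_at", ti != "tissue01"])
    expect_lt(abs(est - 4), 0.3)
})

test_that("mbei recovers the multiplicative model", {
    # noiseless phi * theta with the identifiability constraint holds
    phi <- c(0.5, 1.5, 0.8); phi <- phi / sqrt(sum(phi^2) / 3)
    theta <- c(40, 400, 4000, 100)
    vals <- outer(phi, theta)
    dimnames(vals) <- list(paste0("g1_p", 1:3),
                           paste0("a", 1:4))
    pim <- probeIntensities(vals, data.frame(
        array_id = paste0("a", 1:4), tissue = "t", replicate = 1:4,
        row.names = paste0("a", 1:4)))
    ann <- annotationFromMapping(data.frame(
        probe_id = rownames(vals), probeset_id = "g1_at",
        gene_id = "g1"))
    ex <- mbeiSummarize(pim, ann, normalize = FALSE)
    expect_equal(exprValues(ex)["g1_at", ], log2(theta),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(exprMethod(ex), "mbei")

    # single-probe probeset: theta proportional to the probe's intensities
    one <- vals[1, , drop = FALSE]
    pim1 <- probeIntensities(one, as.data.frame(arrayInfo(pim)))
    ann1 <- annotationFromMapping(data.frame(
        probe_id = rownames(one), probeset_id = "g1_at", gene_id = "g1"))
    ex1 <- mbeiSummarize(pim1, ann1, normalize = FALSE)
    expect_equal(diff(exprValues(ex1)["g1_at", ]), diff(log2(theta)),
                 tolerance = 1e-8, ignore_attr = TRUE)

    # theta ordering survives noise
    set.seed(3)
    noisy <- vals * matrix(exp(rnorm(12, 0, 0.1)), 3)
    pimN <- probeIntensities(noisy, as.data.frame(arrayInfo(pim)))
    exN <- mbeiSummarize(pimN, ann, normalize = FALSE)
    expect_gte(cor(exprValues(exN)["g1_at", ], log2(theta),
                   method = "spearman"), 0.99)

    expect_error(mbeiSummarize(pim1[, 1], ann1), "2 arrays")
})

test_that("both summarization methods track planted tissue contrasts", {
    planted <- data.frame(gene = sprintf("gene%04d", 1:10),
                          tissue = "tissue01",
                          effect = seq(1.5, 4, length.out = 10))
    cfg <- simulationConfig(nGenes = 300, nTissues = 3, pExpressed = 1,
                            replicatesPerTissue = 6,
                            plantedEnriched = planted,
                            nNegativeProbes = 40, seed = 11)
    seqs <- generateSequences(cfg)
    pim <- simulateIntensities(cfg, seqs$truth)
    ann <- annotationFromMapping(seqs$mapping)
    ti <- .tissue <- NULL
    for (ex in list(rmaSummarize(pim, ann), mbeiSummarize(pim, ann))) {
        e <- exprValues(ex)
        ti <- arrayInfo(ex)$tissue
        ids <- paste0(planted$gene, "_at")
        est <- rowMeans(e[ids, ti == "tissue01"]) -
            rowMeans(e[ids, ti != "tissue01"])
        expect_gte(cor(est, planted$effect), 0.95)
    }
})
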