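#' @include AllClasses.R
NULL

#' Pairwise distances between rows or columns
#'
#' @param m numeric matrix, no missing values.
#' @param axis `"rows"` or `"cols"` (items to compare).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return a [stats::dist] object.
#' @export
pairwiseDistance <- function(m, axis = c("rows", "cols"),
                             metric = c("euclidean", "manhattan")) {
    axis <- match.arg(axis); metric <- match.arg(metric)
    m <- as.matrix(m)
    if (anyNA(m) || any(!is.finite(m)))
        stop("distance input must be finite and complete")
    if (axis == "cols") m <- t(m)
    if (nrow(m) < 2L) stop("need at least 2 items")
    stats::dist(m, method = metric)
}

#' Complete-linkage hierarchical agglomerative clustering
#'
#' Naive O(n^3) complete-linkage clustering with a deterministic tie-break:
#' among pairs at the minimal inter-cluster distance, the pair whose
#' (smallest, then second) original leaf indices are lexicographically
#' least is merged. Inter-cluster distance is the maximum pairwise leaf
#' distance, so merge heights are non-decreasing. Returns a standard
#' `hclust` object (usable with [stats::cutree()], plotting, heatmaps).
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @return an object of class `hclust`.
#' @export
hclustComplete <- function(d) {
    dm <- as.matrix(d)
    n <- nrow(dm)
    if (n < 2L) stop("need at least 2 items")
    labels <- rownames(dm)
    active <- seq_len(n)            # cluster ids; 1..n start as leaves
    members <- as.list(seq_len(n))  # leaf indices per cluster
    code <- -seq_len(n)             # hclust merge codes
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    D <- dm

    for (step in seq_len(n - 1L)) {
        best <- NULL; bestKey <- NULL; bestH <- Inf
        for (ii in seq_along(active)) {
            for (jj in seq_along(active)) {
                if (jj <= ii) next
                i <- active[ii]; j <- active[jj]
                h <- D[i, j]
                key <- sort(c(min(members[[i]]), min(members[[j]])))
                if (h < bestH - 1e-12 ||
                    (abs(h - bestH) <= 1e-12 && !is.null(bestKey) &&
                     (key[1] < bestKey[1] ||
                      (key[1] == bestKey[1] && key[2] < bestKey[2])))) {
                    bestH <- h; best <- c(i, j); bestKey <- key
                }
            }
        }
        i <- best[1]; j <- best[2]
        ## hclust convention: singletons (negative codes) first, each kind
        ## ordered by absolute value
        pair <- c(code[i], code[j])
        merge[step, ] <- pair[order(pair >= 0, abs(pair))]
        height[step] <- bestH
        members[[i]] <- c(members[[i]], members[[j]])
        code[i] <- step
        for (k in active)
            if (k != i && k != j)
                D[i, k] <- D[k, i] <- max(D[i, k], D[j, k])
        active <- setdiff(active, j)
    }

    leafOrder <- function(row) {
        unlist(lapply(merge[row, ], function(x)
            if (x < 0) -x else leafOrder(x)))
    }
    structure(list(merge = merge, height = height,
                   order = leafOrder(n - 1L), labels = labels,
                   method = "complete",
                   call = match.call(),
                   dist.method = attr(d, "method")),
              class = "hclust")
}

#' Center and scale matrix rows
#'
#' Subtracts the row mean and divides by the row SD. Because the scaling is
#' used for display only, the population SD (divisor `n`) is used. Constant
#' rows map to all zeros with a warning.
#'
#' @param m numeric matrix with at least one column.
#' @return the scaled matrix.
#' @export
rowScale <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 1L) stop("need at least one column")
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2))
    if (any(s == 0)) {
        warning(sum(s == 0), " constant row(s) scaled to zero")
        s[s == 0] <- 1
    }
    (m - mu) / s
}

#' Render a clustered heatmap and its ordered matrix
#'
#' Reorders the matrix by the dendrogram leaf orders, optionally row-scales
#' it, writes the reordered matrix as TSV (the testable artifact) and, when
#' an image path is given, renders a raster heatmap.
#'
#' @param m numeric matrix with row and column names.
#' @param rowDend,colDend optional `hclust` objects (e.g. from
#'   [hclustComplete()]) whose labels must match the matrix dimnames.
#' @param file optional TSV path for the ordered matrix.
#' @param imageFile optional PNG path.
#' @param scaleRows row-scale before writing/plotting (default `TRUE`).
#' @return invisibly, the reordered (scaled) matrix.
#' @export
renderHeatmap <- function(m, rowDend = NULL, colDend = NULL, file = NULL,
                          imageFile = NULL, scaleRows = TRUE) {
    m <- as.matrix(m)
    checkDend <- function(dend, labs, what) {
        if (!setequal(dend$labels, labs))
            stop(what, " dendrogram labels do not match the matrix")
    }
    ro <- rownames(m); co <- colnames(m)
    if (!is.null(rowDend)) {
        checkDend(rowDend, ro, "row")
        ro <- rowDend$labels[rowDend$order]
    }
    if (!is.null(colDend)) {
        checkDend(colDend, co, "column")
        co <- colDend$labels[colDend$order]
    }
    out <- m[ro, co, drop = FALSE]
    if (scaleRows) out <- rowScale(out)
    if (!is.null(file)) {
        df <- data.frame(id = rownames(out), out, check.names = FALSE)
        utils::write.table(df, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(imageFile)) {
        pheatmap::pheatmap(
            if (scaleRows) rowScale(m) else m,
            cluster_rows = if (is.null(rowDend)) FALSE else rowDend,
            cluster_cols = if (is.null(colDend)) FALSE else colDend,
            filename = imageFile, silent = TRUE)
    }
    invisible(out)
}

#' Cluster atlas samples on gene-level expression
#'
#' Convenience wrapper for replicate-reproducibility checks: drops genes
#' below a variance floor, computes sample pairwise distances and clusters
#' with complete linkage.
#'
#' @param expr a [ProbesetExpression] or genes x arrays matrix.
#' @param metric `"euclidean"` or `"manhattan"` (the sample-clustering
#'   figure convention is manhattan).
#' @param varianceFloor minimum per-gene variance retained (default 1e-12).
#' @return list with `dist` and `hclust`.
#' @export
clusterSamples <- function(expr, metric = c("manhattan", "euclidean"),
                           varianceFloor = 1e-12) {
    metric <- match.arg(metric)
    e <- if (is(expr, "ProbesetExpression")) exprValues(expr)
         else as.matrix(expr)
    v <- apply(e, 1L, stats::var)
    e <- e[v > varianceFloor, , drop = FALSE]
    d <- pairwiseDistance(e, axis = "cols", metric = metric)
    list(dist = d, hclust = hclustComplete(d))
}
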