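#' @include AllClasses.R
NULL

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test of independence for the table
#' `rbind(c(a, b), c(c, d))`. The two-sided p-value sums the point
#' probabilities of all tables with the same margins whose probability does
#' not exceed the observed one (with a small relative slack for floating
#' point ties); `greater`/`less` are the hypergeometric survival/cdf of the
#' top-left cell. A table with an all-zero margin has `p = 1` by
#' convention.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return the p-value.
#' @export
#' @examples
#' fisherExact2x2(2, 0, 0, 2)  # 1/3
fisherExact2x2 <- function(a, b, c, d,
        alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
        return(1)
    stats::fisher.test(matrix(cells, 2L, 2L, byrow = TRUE),
                       alternative = alternative)$p.value
}

#' Family over/under-representation against the array-genome
#'
#' Per family, a two-sided Fisher's exact test on the 2x2 table of
#' (in/out family) x (in/out significant set) over the full gene universe
#' (the "array-genome"). Families with no genes in the universe are skipped
#' with a message.
#'
#' @param sigGenes character vector of significant genes (subset of
#'   `universe`).
#' @param families named list: family id -> character vector of member
#'   genes.
#' @param universe character vector: all genes on the array.
#' @param alpha significance cutoff on the raw two-sided p (default 0.01).
#' @return data.frame with columns `family`, `inFamily`, `sigInFamily`,
#'   `expected`, `oddsRatio` (sample odds ratio; > 1 = over-represented),
#'   `p`, `significant`, ordered by p.
#' @export
familyEnrichment <- function(sigGenes, families, universe, alpha = 0.01) {
    if (!all(sigGenes %in% universe))
        stop("sigGenes must be a subset of the universe")
    families <- lapply(families, intersect, universe)
    empty <- lengths(families) == 0L
    if (any(empty)) {
        message("skipping ", sum(empty), " empty families")
        families <- families[!empty]
    }
    nSig <- length(sigGenes); N <- length(universe)
    rows <- lapply(names(families), function(f) {
        fam <- families[[f]]
        a <- length(intersect(fam, sigGenes))
        b <- length(fam) - a
        c <- nSig - a
        d <- N - length(fam) - c
        orr <- (a * d) / max(b * c, .Machine$double.eps)
        data.frame(family = f, inFamily = length(fam), sigInFamily = a,
                   expected = length(fam) * nSig / N,
                   oddsRatio = orr,
                   p = fisherExact2x2(a, b, c, d, "two.sided"))
    })
    out <- do.call(rbind, rows)
    out$significant <- out$p < alpha
    out[order(out$p), , drop = FALSE]
}

#' Build a GO-style term DAG with direct gene annotations
#'
#' @param parentChild data.frame with columns `child`, `parent` (term ids;
#'   is_a and part_of links are treated alike).
#' @param annotation data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @return a [GoDag] (annotations not yet propagated).
#' @export
goDag <- function(parentChild, annotation) {
    terms <- sort(unique(c(parentChild$child, parentChild$parent,
                           annotation$term)))
    parents <- lapply(stats::setNames(terms, terms), function(t)
        unique(parentChild$parent[parentChild$child == t]))
    direct <- lapply(stats::setNames(terms, terms), function(t)
        unique(annotation$gene[annotation$term == t]))
    new("GoDag", terms = terms, parents = parents,
        directAnnotation = direct, propagated = list())
}

#' Read a minimal OBO subset into a term DAG
#'
#' Parses `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines; both link types become parent links.
#'
#' @param file path to the OBO file.
#' @param annotation data.frame (`gene`, `term`) of direct annotations.
#' @return a [GoDag].
#' @export
readOboDag <- function(file, annotation) {
    lines <- readLines(file)
    child <- parent <- character(0)
    cur <- NA_character_
    for (ln in lines) {
        if (grepl("^\\[", ln)) cur <- NA_character_
        if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
        pa <- NA_character_
        if (grepl("^is_a:", ln))
            pa <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (grepl("^relationship: part_of", ln))
            pa <- trimws(sub("!.*$", "",
                             sub("^relationship: part_of", "", ln)))
        if (!is.na(pa) && !is.na(cur)) {
            child <- c(child, cur); parent <- c(parent, pa)
        }
    }
    goDag(data.frame(child = child, parent = parent), annotation)
}

.dagTopoOrder <- function(dag) {
    edges <- do.call(rbind, lapply(names(dag@parents), function(ch) {
        if (length(dag@parents[[ch]]))
            data.frame(from = ch, to = dag@parents[[ch]])
        else NULL
    }))
    g <- igraph::graph_from_data_frame(
        if (is.null(edges)) data.frame(from = character(0),
                                       to = character(0)) else edges,
        directed = TRUE, vertices = dag@terms)
    if (!igraph::is_dag(g)) {
        comp <- igraph::components(g, mode = "strong")
        cyc <- names(comp$membership)[
            comp$membership %in% which(comp$csize > 1L)]
        stop("cycle detected among terms: ", paste(cyc, collapse = " -> "))
    }
    ## edges run child -> parent, so this order lists children first
    names(igraph::topo_sort(g, mode = "out"))
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Every term's propagated gene set is the union of its direct annotations
#' and the propagated sets of all its children (a gene annotated to a term
#' is implicitly annotated to every ancestor; diamonds do not double-count
#' because sets are unioned). A cycle is an error naming the offending
#' terms.
#'
#' @param dag a [GoDag].
#' @return the [GoDag] with the `propagated` slot filled.
#' @export
propagateAnnotations <- function(dag) {
    ord <- .dagTopoOrder(dag)
    children <- lapply(stats::setNames(dag@terms, dag@terms),
                       function(t) character(0))
    for (ch in names(dag@parents))
        for (pa in dag@parents[[ch]])
            children[[pa]] <- c(children[[pa]], ch)
    prop <- list()
    for (t in ord)  # children precede parents
        prop[[t]] <- unique(c(dag@directAnnotation[[t]],
                              unlist(prop[children[[t]]],
                                     use.names = FALSE)))
    dag@propagated <- prop[dag@terms]
    validObject(dag)
    dag
}

.oneSidedFisher <- function(sigInTerm, inTerm, nSig, N)
    stats::phyper(sigInTerm - 1L, inTerm, N - inTerm, nSig,
                  lower.tail = FALSE)

#' GO term over-representation with optional DAG decorrelation
#'
#' One-sided (over-representation) Fisher tests per term on the propagated
#' annotation sets restricted to the universe, with `Expected =
#' annotated(term) * |sig| / |universe|`. Three scoring methods:
#'
#' * `classic`: each term tested independently of the graph.
#' * `elim`: terms are processed children-before-parents; genes annotated
#'   to a term with `p < alphaElim` are removed from all its ancestors
#'   before those are tested, so significant specific terms do not drag
#'   their ancestors along.
#' * `weight`: child and parent significance is compared term by term and
#'   genes of the locally better-scoring relatives are down-weighted in the
#'   other's weighted Fisher count (see the methods vignette for the exact
#'   scheme); leaves, and siblings sharing no genes, score as in `classic`.
#'
#' @param dag a [GoDag] with propagated annotations (see
#'   [propagateAnnotations()]); un-propagated DAGs are propagated on the
#'   fly.
#' @param sigGenes significant genes (subset of `universe`).
#' @param universe all genes on the array.
#' @param method `"classic"`, `"elim"` or `"weight"`.
#' @param alphaElim elimination threshold for `elim` (default 0.01).
#' @return data.frame with columns `term`, `Annotated`, `Significant`,
#'   `Expected`, `p` (raw p, untruncated) and `p_display` (truncated at
#'   1e-30 as `"<1e-30"`), ordered by p.
#' @export
goEnrichment <- function(dag, sigGenes, universe,
        method = c("classic", "elim", "weight"), alphaElim = 0.01) {
    method <- match.arg(method)
    if (!all(sigGenes %in% universe))
        stop("sigGenes must be a subset of the universe")
    if (!length(dag@propagated)) dag <- propagateAnnotations(dag)
    ann <- lapply(dag@propagated, intersect, universe)
    nSig <- length(sigGenes); N <- length(universe)
    ord <- .dagTopoOrder(dag)  # children first

    ancestorsOf <- function(t) {
        out <- character(0); queue <- dag@parents[[t]]
        while (length(queue)) {
            out <- union(out, queue)
            queue <- setdiff(unique(unlist(dag@parents[queue],
                                           use.names = FALSE)), out)
        }
        out
    }

    p <- stats::setNames(rep(NA_real_, length(dag@terms)), dag@terms)
    if (method == "classic") {
        for (t in dag@terms)
            p[t] <- .oneSidedFisher(length(intersect(ann[[t]], sigGenes)),
                                    length(ann[[t]]), nSig, N)
    } else if (method == "elim") {
        removed <- lapply(stats::setNames(dag@terms, dag@terms),
                          function(t) character(0))
        for (t in ord) {
            genes <- setdiff(ann[[t]], removed[[t]])
            p[t] <- .oneSidedFisher(length(intersect(genes, sigGenes)),
                                    length(genes), nSig, N)
            if (is.finite(p[t]) && p[t] < alphaElim)
                for (anc in ancestorsOf(t))
                    removed[[anc]] <- union(removed[[anc]], ann[[t]])
        }
    } else {
        ## weight: per-term gene weights, children processed first
        weights <- lapply(ann, function(g)
            stats::setNames(rep(1, length(g)), g))
        termP <- function(t) {
            w <- weights[[t]]
            .oneSidedFisher(round(sum(w[names(w) %in% sigGenes])),
                            round(sum(w)), nSig, N)
        }
        children <- lapply(stats::setNames(dag@terms, dag@terms),
                           function(t) character(0))
        for (ch in names(dag@parents))
            for (pa in dag@parents[[ch]])
                children[[pa]] <- c(children[[pa]], ch)
        downWeight <- function(genes, ratio, terms) {
            for (tt in terms) {
                hit <- names(weights[[tt]]) %in% genes
                weights[[tt]][hit] <<- weights[[tt]][hit] * ratio
            }
        }
        for (u in ord) {
            ch <- children[[u]]
            repeat {
                pu <- termP(u)
                if (!length(ch)) break
                pch <- vapply(ch, termP, numeric(1))
                better <- pch < pu
                if (!any(better)) {
                    ## u locally most significant: down-weight children's
                    ## genes in u's ancestors so they do not inherit u's
                    ## signal twice
                    for (cc in ch)
                        downWeight(names(weights[[cc]]), pu / max(pch[cc],
                                   .Machine$double.xmin),
                                   ancestorsOf(u))
                    break
                }
                ## some child explains the signal better: discount its
                ## genes in u and above, then re-examine the rest
                for (cc in ch[better])
                    downWeight(names(weights[[cc]]),
                               pch[cc] / max(pu, .Machine$double.xmin),
                               c(u, ancestorsOf(u)))
                ch <- ch[!better]
            }
            p[u] <- termP(u)
        }
    }
    sig <- vapply(dag@terms, function(t)
        length(intersect(ann[[t]], sigGenes)), integer(1))
    out <- data.frame(
        term = dag@terms,
        Annotated = lengths(ann)[dag@terms],
        Significant = sig,
        Expected = lengths(ann)[dag@terms] * nSig / N,
        p = p[dag@terms], row.names = NULL)
    out$p_display <- ifelse(out$p < 1e-30, "<1e-30",
                            formatC(out$p, format = "g", digits = 3))
    out[order(out$p), , drop = FALSE]
}
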