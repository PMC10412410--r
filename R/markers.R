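#' Candidate marker genes by background-restricted differential expression
#'
#' Step one of the two-step marker method. The target cluster is compared
#' only against the chosen background — typically the clusters it is most
#' closely related to (e.g. the sibling subclusters of the same broad
#' cluster) rather than the whole dataset, so that subtle differences
#' between a rare population and its neighbours are not drowned out. Each
#' gene gets a two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction) of target versus background on normalised expression,
#' Benjamini-Hochberg correction across tested genes, and a log2
#' fold-change of mean expression computed on the de-logged scale with a
#' pseudocount of 1. Candidates are genes with `p_adj < alpha` and
#' `log2_fc > minLFC`.
#'
#' @param x A `SingleCellExperiment` with a `logcounts` assay, or a
#'   genes-by-cells normalised matrix.
#' @param labels Cluster labels (factor/character named by cell id, in cell
#'   order, or a label table).
#' @param target Target cluster label.
#' @param background Character vector of background cluster labels; must
#'   not contain `target`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param minLFC Minimum log2 fold-change (default 0.25).
#' @return A `data.frame` (one row per candidate gene, sorted by descending
#'   `log2_fc`) with columns `gene_id`, `log2_fc`, `p`, `p_adj`,
#'   `pct_target`, `pct_background`, `passed_filter` (initialised `TRUE`;
#'   see [filterMarkers()]).
#' @export
setGeneric("candidateMarkers",
    function(x, labels, target, background, alpha = 0.05, minLFC = 0.25)
        standardGeneric("candidateMarkers"))

#' @rdname candidateMarkers
#' @export
setMethod("candidateMarkers", "ANY",
    function(x, labels, target, background, alpha = 0.05, minLFC = 0.25) {
    norm <- x
    if (is.null(colnames(norm)))
        colnames(norm) <- paste0("cell", seq_len(ncol(norm)))
    if (is.null(rownames(norm)))
        rownames(norm) <- paste0("gene", seq_len(nrow(norm)))
    labels <- .alignLabels(labels, colnames(norm))
    if (target %in% background)
        stop("target must not be part of the background")
    tcells <- which(labels == target)
    bcells <- which(labels %in% background)
    if (!length(tcells)) stop("target cluster is empty")
    if (!length(bcells)) stop("background is empty")

    tm <- as.matrix(norm[, tcells, drop = FALSE])
    bm <- as.matrix(norm[, bcells, drop = FALSE])
    p <- .wilcoxonVec(tm, bm)
    p_adj <- stats::p.adjust(p, method = "BH")
    lfc <- log2((rowMeans(expm1(tm)) + 1) / (rowMeans(expm1(bm)) + 1))
    out <- data.frame(
        gene_id = rownames(norm),
        log2_fc = lfc,
        p = p,
        p_adj = p_adj,
        pct_target = rowMeans(tm > 0),
        pct_background = rowMeans(bm > 0),
        passed_filter = TRUE,
        stringsAsFactors = FALSE)
    out <- out[out$p_adj < alpha & out$log2_fc > minLFC, , drop = FALSE]
    out <- out[order(-out$log2_fc), , drop = FALSE]
    rownames(out) <- NULL
    out
})

#' @rdname candidateMarkers
#' @export
setMethod("candidateMarkers", "SingleCellExperiment",
    function(x, labels, target, background, alpha = 0.05, minLFC = 0.25) {
        candidateMarkers(SummarizedExperiment::assay(x, "logcounts"),
                         labels, target, background,
                         alpha = alpha, minLFC = minLFC)
    })

# Vectorised two-sided Wilcoxon rank-sum, normal approximation with tie
# correction; matches wilcox.test(exact = FALSE, correct = FALSE).
.wilcoxonVec <- function(tm, bm) {
    n1 <- ncol(tm); n2 <- ncol(bm); n <- n1 + n2
    xx <- cbind(tm, bm)
    p <- vapply(seq_len(nrow(xx)), function(g) {
        r <- rank(xx[g, ])
        W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        ties <- table(xx[g, ])
        tiecor <- sum(ties^3 - ties) / (n * (n - 1))
        sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
        if (sigma2 <= 0) return(1)
        z <- (W - n1 * n2 / 2) / sqrt(sigma2)
        2 * stats::pnorm(-abs(z))
    }, numeric(1))
    pmin(p, 1)
}

#' Per-cluster top-expressed gene sets
#'
#' For every cluster, the `ceiling(pct * n_genes)` genes with the highest
#' mean normalised expression over that cluster's cells — the operational
#' definition of "highly expressed in a cluster" used by the marker filter.
#'
#' @inheritParams candidateMarkers
#' @param pct Percentile cutoff in `(0, 1)` (default 0.10, i.e. top 10%).
#' @return A named list of character vectors, one per cluster.
#' @export
setGeneric("topExpressedSets",
    function(x, labels, pct = 0.10) standardGeneric("topExpressedSets"))

#' @rdname topExpressedSets
#' @export
setMethod("topExpressedSets", "ANY", function(x, labels, pct = 0.10) {
    if (pct <= 0 || pct >= 1)
        stop("parameter error: pct must be in (0, 1)")
    norm <- x
    if (is.null(colnames(norm)))
        colnames(norm) <- paste0("cell", seq_len(ncol(norm)))
    if (is.null(rownames(norm)))
        rownames(norm) <- paste0("gene", seq_len(nrow(norm)))
    labels <- .alignLabels(labels, colnames(norm))
    ntop <- ceiling(pct * nrow(norm))
    sets <- lapply(levels(labels), function(cl) {
        mu <- Matrix::rowMeans(norm[, labels == cl, drop = FALSE])
        rownames(norm)[order(mu, decreasing = TRUE)[seq_len(ntop)]]
    })
    stats::setNames(sets, levels(labels))
})

#' @rdname topExpressedSets
#' @export
setMethod("topExpressedSets", "SingleCellExperiment",
    function(x, labels, pct = 0.10) {
        topExpressedSets(SummarizedExperiment::assay(x, "logcounts"),
                         labels, pct = pct)
    })

#' Filter candidate markers for cluster specificity
#'
#' Step two of the marker method: a candidate gene is rejected if it is
#' among the top-expressed genes of any cluster *other than* the target and
#' the exempt set. By default the exempt set is the background clusters of
#' the differential-expression step (they were contrasted directly, so high
#' expression there already lowered the fold-change); `exempt = character()`
#' gives the strict behaviour where only the target itself is exempt. This
#' removes genes that are merely ubiquitously high (e.g. housekeeping
#' genes) no matter how large their fold-change against a particular
#' background.
#'
#' @param candidates Candidate table from [candidateMarkers()].
#' @param topSets Per-cluster top-expressed sets from [topExpressedSets()];
#'   must cover every cluster.
#' @param target Target cluster label.
#' @param exempt Character vector of clusters whose high expressers are not
#'   held against a candidate (default: the DE background).
#' @return The candidate table with `passed_filter` updated, rows with
#'   `passed_filter == TRUE` first (still sorted by descending `log2_fc`
#'   within each group). Never adds genes.
#' @export
filterMarkers <- function(candidates, topSets, target,
                          exempt = character()) {
    foreign <- setdiff(names(topSets), c(target, exempt))
    disallowed <- unique(unlist(topSets[foreign], use.names = FALSE))
    candidates$passed_filter <- !(candidates$gene_id %in% disallowed)
    candidates[order(-candidates$passed_filter, -candidates$log2_fc), ,
               drop = FALSE]
}

#' Specificity-filtered markers for one cluster
#'
#' Convenience wrapper running both steps: background-restricted
#' differential expression, then the top-expressed specificity filter.
#'
#' @inheritParams candidateMarkers
#' @param pct Percentile cutoff for [topExpressedSets()].
#' @param strict If `TRUE`, no cluster is exempt from the filter besides
#'   the target; by default the DE background is exempt.
#' @return A marker `data.frame` as in [filterMarkers()].
#' @export
specificMarkers <- function(x, labels, target, background,
                            alpha = 0.05, minLFC = 0.25, pct = 0.10,
                            strict = FALSE) {
    cand <- candidateMarkers(x, labels, target, background,
                             alpha = alpha, minLFC = minLFC)
    tops <- topExpressedSets(x, labels, pct = pct)
    filterMarkers(cand, tops, target,
                  exempt = if (strict) character() else background)
}
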