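#' k-nearest-neighbour indices in an embedding
#'
#' Euclidean k-nearest neighbours computed blockwise. Each cell's neighbour
#' set includes the cell itself (the shared-nearest-neighbour convention),
#' so `k` neighbours means the cell plus its `k - 1` nearest others.
#'
#' @param emb Cells-by-d embedding matrix.
#' @param k Neighbourhood size including self; `2 <= k < n_cells`.
#' @param block Rows per block.
#' @return An n-by-k integer matrix of neighbour indices; column 1 is the
#'   cell itself.
#' @keywords internal
.knnIndices <- function(emb, k, block = 512L) {
    n <- nrow(emb)
    sq <- rowSums(emb^2)
    out <- matrix(0L, n, k)
    for (start in seq(1L, n, by = block)) {
        idx <- start:min(start + block - 1L, n)
        d2 <- outer(sq[idx], sq, `+`) -
              2 * tcrossprod(emb[idx, , drop = FALSE], emb)
        d2[cbind(seq_along(idx), idx)] <- -Inf   # self always first
        out[idx, ] <- t(apply(d2, 1, function(v)
            order(v)[seq_len(k)]))
    }
    out
}

#' Build a shared-nearest-neighbour graph
#'
#' Computes Euclidean k-nearest neighbours in the embedding (each cell's
#' neighbour set including itself) and connects cells by the Jaccard overlap
#' of their neighbour sets: `w(i, j) = |N_i ∩ N_j| / |N_i ∪ N_j|`. Edges
#' with weight at or below `prune` are removed. This is the substrate for
#' modularity-based community detection.
#'
#' @param emb Cells-by-d embedding matrix (rownames used as vertex names),
#'   or a `SingleCellExperiment` with a `"PCA"` reduced dimension.
#' @param k Neighbourhood size, `2 <= k < n_cells` (default 20).
#' @param prune Jaccard cutoff; edges with weight `<= prune` are dropped
#'   (default `1/15`).
#' @return An undirected weighted [igraph::graph] with one vertex per cell,
#'   edge weights in `(0, 1]` and no self-loops.
#' @export
setGeneric("snnGraph",
    function(emb, k = 20L, prune = 1/15)
        standardGeneric("snnGraph"))

#' @rdname snnGraph
#' @export
setMethod("snnGraph", "ANY", function(emb, k = 20L, prune = 1/15) {
    emb <- as.matrix(emb)
    n <- nrow(emb)
    if (k < 2 || k >= n)
        stop("k must satisfy 2 <= k < n_cells (n_cells = ", n, ")")
    nn <- .knnIndices(emb, as.integer(k))
    adj <- Matrix::sparseMatrix(
        i = rep(seq_len(n), each = k),
        j = as.integer(t(nn)),
        x = 1, dims = c(n, n))
    inter <- Matrix::tcrossprod(adj)           # |N_i ∩ N_j|
    inter <- methods::as(inter, "TsparseMatrix")
    keep <- inter@i < inter@j
    i <- inter@i[keep] + 1L
    j <- inter@j[keep] + 1L
    ov <- inter@x[keep]
    w <- ov / (2 * k - ov)                     # Jaccard, |N_i| = |N_j| = k
    pass <- w > prune
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (any(pass))
        g <- igraph::add_edges(g, rbind(i[pass], j[pass]),
                               weight = w[pass])
    nms <- rownames(emb)
    if (is.null(nms)) nms <- paste0("cell", seq_len(n))
    igraph::set_vertex_attr(g, "name", value = nms)
})

#' @rdname snnGraph
#' @export
setMethod("snnGraph", "SingleCellExperiment",
    function(emb, k = 20L, prune = 1/15) {
        snnGraph(SingleCellExperiment::reducedDim(emb, "PCA"),
                 k = k, prune = prune)
    })

#' Modularity-based community detection on an SNN graph
#'
#' Runs Leiden (default) or Louvain modularity optimisation at resolution
#' `r` on a weighted SNN graph. Larger `r` yields more, smaller
#' communities; the conservative broad pass of the pipeline uses a small
#' `r`. Labels are canonicalised to `"0" ... "K-1"` by decreasing community
#' size, ties broken by the smallest member vertex index, so runs are
#' comparable. Deterministic for a fixed `seed`.
#'
#' A graph with no edges yields one singleton community per cell, with a
#' warning.
#'
#' @param graph An [igraph::graph] from [snnGraph()].
#' @param r Resolution parameter (default 0.3 — the conservative broad-pass
#'   default).
#' @param seed Integer seed.
#' @param algorithm `"leiden"` (default) or `"louvain"`.
#' @return A factor of cluster labels named by vertex (cell id).
#' @export
communityDetect <- function(graph, r = 0.3, seed = 1L,
                            algorithm = c("leiden", "louvain")) {
    algorithm <- match.arg(algorithm)
    n <- igraph::vcount(graph)
    if (n == 0) stop("empty graph")
    nms <- igraph::vertex_attr(graph, "name")
    if (is.null(nms)) nms <- as.character(seq_len(n))
    if (igraph::ecount(graph) == 0) {
        warning("SNN graph has no edges; every cell is its own community")
        memb <- seq_len(n)
    } else {
        set.seed(as.integer(seed) %% .Machine$integer.max)
        comm <- switch(algorithm,
            leiden = igraph::cluster_leiden(
                graph, objective_function = "modularity",
                weights = igraph::E(graph)$weight,
                resolution = r, n_iterations = 5),
            louvain = igraph::cluster_louvain(
                graph, weights = igraph::E(graph)$weight,
                resolution = r))
        memb <- igraph::membership(comm)
    }
    stats::setNames(.canonicalizeLabels(memb), nms)
}

# Relabel communities as "0".."K-1" by decreasing size, ties by smallest
# member index.
.canonicalizeLabels <- function(memb) {
    memb <- as.integer(factor(memb))
    sizes <- tabulate(memb)
    firsts <- vapply(seq_along(sizes), function(cl)
        which(memb == cl)[1], integer(1))
    ord <- order(-sizes, firsts)
    newlab <- integer(length(sizes))
    newlab[ord] <- seq_along(sizes) - 1L
    factor(newlab[memb], levels = seq_along(sizes) - 1L)
}
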