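#' Cosine distance between two vectors
#'
#' `1 - (a . b) / (||a|| ||b||)`, bounded in `[0, 2]`: 0 for parallel, 1 for
#' orthogonal, 2 for antiparallel vectors. Defined only for non-zero
#' vectors; a zero vector is a domain error (never a silent `NaN`).
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single number in `[0, 2]`.
#' @examples
#' cosineDistance(c(1, 2, 3), c(2, 4, 6))  # 0
#' cosineDistance(c(1, 0), c(0, 1))        # 1
#' @export
cosineDistance <- function(a, b) {
    if (length(a) != length(b)) stop("vectors must have equal length")
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
        stop("cosine distance is undefined for zero vectors")
    d <- 1 - sum(a * b) / (na * nb)
    min(max(d, 0), 2)
}

# L2-normalise rows; errors naming the first zero-norm row.
.rowUnit <- function(emb) {
    nrm <- sqrt(rowSums(emb^2))
    if (any(nrm == 0)) {
        bad <- which(nrm == 0)[1]
        nm <- rownames(emb)[bad]
        stop("zero-norm embedding row for cell ",
             if (is.null(nm)) bad else nm)
    }
    emb / nrm
}

#' Pairwise cosine distance matrix
#'
#' Vectorised all-against-all cosine distance over the rows of an embedding,
#' computed in row blocks so peak memory stays bounded by the block size.
#'
#' @param emb A cells-by-d numeric matrix with no zero rows.
#' @param block Number of rows per block (default 512).
#' @return A symmetric n-by-n matrix with zero diagonal.
#' @export
cosineDistanceMatrix <- function(emb, block = 512L) {
    emb <- as.matrix(emb)
    u <- .rowUnit(emb)
    n <- nrow(u)
    d <- matrix(0, n, n, dimnames = list(rownames(emb), rownames(emb)))
    for (start in seq(1L, n, by = block)) {
        idx <- start:min(start + block - 1L, n)
        d[idx, ] <- 1 - tcrossprod(u[idx, , drop = FALSE], u)
    }
    d <- pmin(pmax(d, 0), 2)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d
}

#' Per-cell silhouette scores on cosine distances
#'
#' For every cell `i` in cluster `C_m`, computes the mean cosine distance
#' `a(i)` to the other members of `C_m` (divisor `|C_m| - 1`), the minimum
#' over other clusters `C_l` of the mean distance `b(i)` to their members,
#' and the silhouette score `s(i) = (b(i) - a(i)) / max(a(i), b(i))`.
#' Per-cluster silhouette coefficients (means) and medians are attached via
#' [clusterCoefficients()]. A low median marks a heterogeneous cluster — the
#' decision statistic that flags reclustering candidates.
#'
#' Cells in singleton clusters get the conventional `s = 0` (with `a = NA`).
#' At least two clusters, one of them non-singleton, are required.
#'
#' For datasets above `cap` cells the scores are estimated on a seeded
#' uniform per-cluster subsample (at least `minPerCluster` cells per
#' cluster, never more than the cluster holds), since the exact computation
#' is quadratic in the number of cells; the report then covers the
#' subsampled cells only and is flagged as subsampled.
#'
#' @param x A cells-by-d embedding matrix, or a `SingleCellExperiment` with
#'   a `"PCA"` reduced dimension.
#' @param labels Cluster labels: a factor/character vector (named by cell id
#'   or in cell order), or a label `data.frame` from [readLabels()].
#' @param cap Cell-count cap above which subsampling kicks in
#'   (default 10000).
#' @param minPerCluster Minimum cells retained per cluster when subsampling
#'   (default 50).
#' @param seed Seed for the subsample draw.
#' @param block Block size passed to the distance computation.
#' @return A [SilhouetteReport-class].
#' @export
setGeneric("silhouetteSamples",
    function(x, labels, cap = 10000L, minPerCluster = 50L, seed = 1L,
             block = 512L)
        standardGeneric("silhouetteSamples"))

#' @rdname silhouetteSamples
#' @export
setMethod("silhouetteSamples", "ANY",
    function(x, labels, cap = 10000L, minPerCluster = 50L, seed = 1L,
             block = 512L) {
    emb <- as.matrix(x)
    if (is.null(rownames(emb)))
        rownames(emb) <- paste0("cell", seq_len(nrow(emb)))
    labels <- .alignLabels(labels, rownames(emb))
    labels <- droplevels(labels)
    K <- nlevels(labels)
    if (K < 2)
        stop("silhouette is undefined for a single cluster ",
             "(no between-cluster distance b)")
    sizes <- table(labels)
    if (all(sizes <= 1))
        stop("at least one cluster must have more than one cell")

    subsampled <- FALSE
    if (nrow(emb) > cap) {
        subsampled <- TRUE
        set.seed(as.integer(seed) %% .Machine$integer.max)
        keep <- unlist(lapply(levels(labels), function(cl) {
            idx <- which(labels == cl)
            take <- max(min(length(idx), minPerCluster),
                        round(length(idx) * cap / nrow(emb)))
            if (take >= length(idx)) idx else sort(sample(idx, take))
        }), use.names = FALSE)
        keep <- sort(keep)
        emb <- emb[keep, , drop = FALSE]
        labels <- droplevels(labels[keep])
        sizes <- table(labels)
    }

    n <- nrow(emb)
    u <- .rowUnit(emb)
    z <- stats::model.matrix(~ 0 + labels)     # n x K indicator
    cnt <- as.numeric(sizes)
    own <- as.integer(labels)

    a <- numeric(n); b <- numeric(n)
    for (start in seq(1L, n, by = block)) {
        idx <- start:min(start + block - 1L, n)
        dblk <- 1 - tcrossprod(u[idx, , drop = FALSE], u)
        dblk <- pmin(pmax(dblk, 0), 2)
        dblk[cbind(seq_along(idx), idx)] <- 0
        sums <- dblk %*% z                     # block x K per-cluster sums
        m <- sweep(sums, 2, cnt, `/`)
        ao <- sums[cbind(seq_along(idx), own[idx])] /
              pmax(cnt[own[idx]] - 1, 1)
        m[cbind(seq_along(idx), own[idx])] <- Inf
        a[idx] <- ao
        b[idx] <- apply(m, 1, min)
    }
    s <- (b - a) / pmax(a, b)
    singleton <- cnt[own] == 1
    a[singleton] <- NA_real_
    s[singleton] <- 0
    s[!is.finite(s)] <- 0                      # a == b == 0 (duplicate rows)

    perCell <- S4Vectors::DataFrame(
        cell_id = rownames(emb),
        cluster = as.character(labels),
        a = a, b = b, s = s)
    rep <- methods::new("SilhouetteReport", perCell = perCell,
                        perCluster = S4Vectors::DataFrame(
                            cluster = character(), n = integer(),
                            coef = numeric(), median = numeric()),
                        subsampled = subsampled)
    clusterCoefficients(rep)
})

#' @rdname silhouetteSamples
#' @export
setMethod("silhouetteSamples", "SingleCellExperiment",
    function(x, labels, cap = 10000L, minPerCluster = 50L, seed = 1L,
             block = 512L) {
        silhouetteSamples(SingleCellExperiment::reducedDim(x, "PCA"),
                          labels, cap = cap, minPerCluster = minPerCluster,
                          seed = seed, block = block)
    })

#' Per-cluster silhouette coefficient and median
#'
#' The silhouette coefficient of a cluster is the mean of its cells'
#' silhouette scores; the median is the flagging statistic. Recomputes the
#' per-cluster table of a [SilhouetteReport-class] from its per-cell scores.
#'
#' @param report A `SilhouetteReport`.
#' @return The report with its `perCluster` table filled in (clusters in
#'   label order).
#' @export
clusterCoefficients <- function(report) {
    pc <- report@perCell
    cl <- factor(pc$cluster)
    co <- tapply(pc$s, cl, mean)
    md <- tapply(pc$s, cl, stats::median)
    report@perCluster <- S4Vectors::DataFrame(
        cluster = levels(cl),
        n = as.integer(table(cl)),
        coef = as.numeric(co),
        median = as.numeric(md))
    methods::validObject(report)
    report
}

#' Write a silhouette report as TSV
#'
#' Writes the per-cell table (`cell_id`, `cluster`, `a`, `b`, `s`) to
#' `cellPath` and, if given, the per-cluster summary (`cluster`, `n`,
#' `coef`, `median`) to `clusterPath`.
#'
#' @param report A [SilhouetteReport-class].
#' @param cellPath,clusterPath Output paths (`clusterPath` optional).
#' @return `cellPath`, invisibly.
#' @export
writeSilhouetteReport <- function(report, cellPath, clusterPath = NULL) {
    utils::write.table(as.data.frame(report@perCell), cellPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(clusterPath))
        utils::write.table(as.data.frame(report@perCluster), clusterPath,
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(cellPath)
}
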