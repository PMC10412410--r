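#' Log-normalise raw counts
#'
#' Per-cell library-size normalisation followed by a log transform:
#' `log(1 + scaleFactor * count / cellTotal)`, so each cell's normalised
#' vector is invariant to scaling its counts and zeros stay zero.
#'
#' Cells with a total count of zero carry no information and, by default,
#' are dropped with a warning (`dropEmpty = FALSE` raises an error instead).
#'
#' @param x A `SingleCellExperiment` with a `counts` assay, or a
#'   genes-by-cells count matrix (dense or sparse).
#' @param scaleFactor Positive scale constant (default `1e4`, i.e. counts
#'   per ten thousand).
#' @param dropEmpty Drop all-zero cells with a warning (default) or error.
#' @return For a `SingleCellExperiment`, the object with a `logcounts`
#'   assay added (possibly with empty cells removed); for a matrix, the
#'   normalised genes-by-cells matrix.
#' @export
setGeneric("logNormalize",
    function(x, scaleFactor = 1e4, dropEmpty = TRUE)
        standardGeneric("logNormalize"))

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "ANY", function(x, scaleFactor = 1e4,
                                          dropEmpty = TRUE) {
    if (scaleFactor <= 0) stop("scaleFactor must be positive")
    totals <- Matrix::colSums(x)
    empty <- totals == 0
    if (any(empty)) {
        if (!dropEmpty)
            stop(sum(empty), " cells have zero total counts")
        warning("dropping ", sum(empty), " cells with zero total counts")
        x <- x[, !empty, drop = FALSE]
        totals <- totals[!empty]
    }
    if (methods::is(x, "sparseMatrix")) {
        m <- methods::as(x, "CsparseMatrix")
        # scale column-wise, then log1p on the nonzero entries only
        fac <- scaleFactor / totals
        m@x <- log1p(m@x * rep.int(fac, diff(m@p)))
        m
    } else {
        log1p(sweep(as.matrix(x), 2, scaleFactor / totals, `*`))
    }
})

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "SingleCellExperiment",
    function(x, scaleFactor = 1e4, dropEmpty = TRUE) {
        counts <- SummarizedExperiment::assay(x, "counts")
        norm <- logNormalize(counts, scaleFactor, dropEmpty)
        if (ncol(norm) != ncol(x))
            x <- x[, colnames(norm)]
        SummarizedExperiment::assay(x, "logcounts") <- norm
        x
    })

#' Select highly variable genes
#'
#' Ranks genes by a variability score computed on the matrix it is given,
#' so calling it on a cluster subset re-derives the feature set locally —
#' the mechanism by which genes that are flat globally but variable within
#' one broad cluster re-enter the analysis during reclustering.
#'
#' Two scores are available. `"vst"` (default) fits a loess trend of
#' log10-variance on log10-mean, standardises each gene by the trend's
#' expected standard deviation with values clipped at `sqrt(n_cells)`, and
#' scores genes by the variance of the standardised values (a
#' variance-stabilised score in which a constant gene scores 0).
#' `"dispersion"` is the simpler variance/mean ratio on the de-logged
#' scale; it is transparent but biased towards highly expressed genes.
#'
#' @param x A `SingleCellExperiment` with a `logcounts` assay, or a
#'   genes-by-cells normalised matrix.
#' @param nHVGs Number of genes to retain (default 2000, capped at the
#'   number of genes).
#' @param method `"vst"` or `"dispersion"`.
#' @return A `data.frame` with columns `gene_id` and `score`, ordered by
#'   decreasing score, with `nHVGs` rows.
#' @export
setGeneric("selectHVGs",
    function(x, nHVGs = 2000, method = c("vst", "dispersion"))
        standardGeneric("selectHVGs"))

#' @rdname selectHVGs
#' @export
setMethod("selectHVGs", "ANY", function(x, nHVGs = 2000,
                                        method = c("vst", "dispersion")) {
    method <- match.arg(method)
    if (nHVGs <= 0) stop("nHVGs must be positive")
    if (nHVGs > nrow(x)) stop("nHVGs exceeds the number of genes")
    if (is.null(rownames(x)))
        rownames(x) <- paste0("gene", seq_len(nrow(x)))
    score <- switch(method,
        vst = .vstScores(x),
        dispersion = .dispersionScores(x))
    ord <- order(score, decreasing = TRUE)
    out <- data.frame(gene_id = rownames(x)[ord], score = score[ord],
                      stringsAsFactors = FALSE)[seq_len(nHVGs), ]
    rownames(out) <- NULL
    out
})

#' @rdname selectHVGs
#' @export
setMethod("selectHVGs", "SingleCellExperiment",
    function(x, nHVGs = 2000, method = c("vst", "dispersion")) {
        selectHVGs(SummarizedExperiment::assay(x, "logcounts"),
                   nHVGs = nHVGs, method = method)
    })

.rowMeansVars <- function(x) {
    n <- ncol(x)
    mu <- Matrix::rowMeans(x)
    ex2 <- Matrix::rowMeans(x^2)
    v <- (ex2 - mu^2) * n / (n - 1)
    list(mean = mu, var = pmax(v, 0))
}

.vstScores <- function(x) {
    n <- ncol(x)
    mv <- .rowMeansVars(x)
    score <- numeric(nrow(x))
    ok <- mv$var > 0 & mv$mean > 0
    if (sum(ok) >= 10) {
        # robust fit so genuinely variable genes cannot drag the trend
        # towards themselves; span widens for small gene sets
        span <- max(0.3, min(1, 30 / sum(ok)))
        fit <- stats::loess(log10(v) ~ log10(m),
                            data = data.frame(v = mv$var[ok], m = mv$mean[ok]),
                            span = span, degree = 2,
                            family = "symmetric")
        sd_exp <- sqrt(10^stats::fitted(fit))
        clipmax <- sqrt(n)
        xok <- as.matrix(x[ok, , drop = FALSE])
        z <- (xok - mv$mean[ok]) / sd_exp
        z <- pmin(pmax(z, -clipmax), clipmax)
        score[ok] <- apply(z, 1, stats::var)
    } else {
        # too few informative genes for a trend; fall back to raw variance
        score[ok] <- mv$var[ok]
    }
    score
}

# dispersion (variance / mean) on the de-logged scale; simple and
# mean-biased, kept as the transparent alternative to the vst score
.dispersionScores <- function(x) {
    ex <- expm1(as.matrix(x))
    mu <- rowMeans(ex)
    v <- apply(ex, 1, stats::var)
    ifelse(mu > 0, v / mu, 0)
}

#' Compute the PCA embedding used by clustering and silhouette scoring
#'
#' Restricts the normalised matrix to the selected highly variable genes,
#' z-scores each gene across cells with values clipped at +/-10 to bound
#' outlier leverage, and projects cells onto the top principal components.
#' The decomposition is exact (base SVD) and therefore deterministic; the
#' `seed` argument is part of the reproducibility contract and is applied
#' before the decomposition.
#'
#' @param x A `SingleCellExperiment` with a `logcounts` assay, or a
#'   genes-by-cells normalised matrix.
#' @param hvgs A `data.frame` from [selectHVGs()], a character vector of
#'   gene ids, or `NULL` to use all genes.
#' @param nPCs Number of components (default 30); must be smaller than both
#'   the number of cells and the number of selected genes.
#' @param seed Integer seed.
#' @return For a matrix, a cells-by-`nPCs` coordinate matrix (rownames are
#'   cell ids). For a `SingleCellExperiment`, the object with the embedding
#'   stored in `reducedDim(x, "PCA")`.
#' @export
setGeneric("computeEmbedding",
    function(x, hvgs = NULL, nPCs = 30, seed = 1L)
        standardGeneric("computeEmbedding"))

#' @rdname computeEmbedding
#' @export
setMethod("computeEmbedding", "ANY", function(x, hvgs = NULL, nPCs = 30,
                                              seed = 1L) {
    genes <- .hvgIds(hvgs, rownames(x))
    m <- x[genes, , drop = FALSE]
    if (nPCs >= min(ncol(m), nrow(m)))
        stop("nPCs must be smaller than both the number of cells and the ",
             "number of selected genes")
    if (nPCs < 2) stop("nPCs must be at least 2")
    z <- .clippedZScores(m)      # cells x genes
    set.seed(as.integer(seed) %% .Machine$integer.max)
    pc <- stats::prcomp(z, center = TRUE, scale. = FALSE, rank. = nPCs)
    coords <- pc$x[, seq_len(nPCs), drop = FALSE]
    # fix component signs so the decomposition has a canonical orientation
    flip <- apply(coords, 2, function(v) v[which.max(abs(v))] < 0)
    coords[, flip] <- -coords[, flip]
    rownames(coords) <- colnames(m)
    colnames(coords) <- paste0("PC", seq_len(nPCs))
    if (any(!is.finite(coords))) stop("non-finite embedding coordinates")
    coords
})

#' @rdname computeEmbedding
#' @export
setMethod("computeEmbedding", "SingleCellExperiment",
    function(x, hvgs = NULL, nPCs = 30, seed = 1L) {
        coords <- computeEmbedding(
            SummarizedExperiment::assay(x, "logcounts"),
            hvgs = hvgs, nPCs = nPCs, seed = seed)
        SingleCellExperiment::reducedDim(x, "PCA") <- coords
        x
    })

.hvgIds <- function(hvgs, all_genes) {
    if (is.null(hvgs)) return(all_genes)
    ids <- if (is.data.frame(hvgs)) hvgs$gene_id else as.character(hvgs)
    bad <- setdiff(ids, all_genes)
    if (length(bad))
        stop("HVG ids not present in matrix: ", paste(utils::head(bad, 3),
             collapse = ", "))
    ids
}

# z-score genes across cells, clip at +/-10; returns dense cells x genes
.clippedZScores <- function(m, clip = 10) {
    mm <- t(as.matrix(m))                      # cells x genes
    mu <- colMeans(mm)
    sd <- apply(mm, 2, stats::sd)
    sd[sd == 0] <- 1                           # constant genes -> all zeros
    z <- sweep(sweep(mm, 2, mu, `-`), 2, sd, `/`)
    pmin(pmax(z, -clip), clip)
}
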