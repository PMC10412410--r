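#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Per-cell and per-cluster silhouette results
#'
#' Container for cosine-distance silhouette scoring of a clustering. The
#' per-cell table holds, for every scored cell, the mean intra-cluster
#' distance `a`, the minimum mean inter-cluster distance `b`, and the
#' silhouette score `s = (b - a) / max(a, b)`. The per-cluster table holds
#' the cluster sizes, the silhouette coefficient (mean of `s` over the
#' cluster) and the median of `s` — the statistic used to flag heterogeneous
#' clusters for reclustering.
#'
#' Cells belonging to singleton clusters have no defined intra-cluster
#' distance; they carry `a = NA` and the conventional score `s = 0`.
#'
#' @slot perCell A [S4Vectors::DataFrame] with columns `cell_id`, `cluster`,
#'   `a`, `b`, `s`.
#' @slot perCluster A [S4Vectors::DataFrame] with columns `cluster`, `n`,
#'   `coef`, `median`.
#' @slot subsampled Logical; `TRUE` when scores were estimated on a seeded
#'   per-cluster subsample rather than on all cells.
#'
#' @seealso [silhouetteSamples()], [clusterCoefficients()]
#' @export
setClass("SilhouetteReport",
    slots = c(
        perCell    = "DataFrame",
        perCluster = "DataFrame",
        subsampled = "logical"
    )
)

setValidity("SilhouetteReport", function(object) {
    pc <- object@perCell
    need <- c("cell_id", "cluster", "a", "b", "s")
    if (!all(need %in% colnames(pc)))
        return(sprintf("perCell must have columns %s",
                       paste(need, collapse = ", ")))
    s <- pc$s
    if (any(!is.na(s) & (s < -1 - 1e-12 | s > 1 + 1e-12)))
        return("silhouette scores must lie in [-1, 1]")
    if (any(!is.na(pc$a) & pc$a < 0) || any(!is.na(pc$b) & pc$b < 0))
        return("distances a and b must be non-negative")
    need2 <- c("cluster", "n", "coef", "median")
    if (!all(need2 %in% colnames(object@perCluster)))
        return(sprintf("perCluster must have columns %s",
                       paste(need2, collapse = ", ")))
    TRUE
})

#' @describeIn SilhouetteReport Per-cell silhouette table.
#' @param x,object A `SilhouetteReport`.
#' @export
setGeneric("cellScores", function(x) standardGeneric("cellScores"))

#' @rdname SilhouetteReport
#' @export
setMethod("cellScores", "SilhouetteReport", function(x) x@perCell)

#' @describeIn SilhouetteReport Per-cluster summary table (n, coefficient,
#'   median score).
#' @export
setGeneric("clusterScores", function(x) standardGeneric("clusterScores"))

#' @rdname SilhouetteReport
#' @export
setMethod("clusterScores", "SilhouetteReport", function(x) x@perCluster)

setMethod("show", "SilhouetteReport", function(object) {
    cs <- object@perCluster
    cat(sprintf("SilhouetteReport: %d cells in %d clusters%s\n",
                nrow(object@perCell), nrow(cs),
                if (object@subsampled) " (subsampled)" else ""))
    df <- as.data.frame(cs)
    df$coef <- round(df$coef, 3)
    df$median <- round(df$median, 3)
    print(df, row.names = FALSE)
    invisible(NULL)
})

#' Result of a silhouette-optimised reclustering of one candidate
#'
#' Produced by [reclusterOne()]. Records the candidate broad cluster(s), the
#' evaluated parameter grid with the silhouette coefficient achieved by each
#' parameter set, the winning parameter set (the argmax; `NA` when no grid
#' point produced more than one admissible subcluster), and the winning
#' sub-labels for the candidate's cells.
#'
#' @slot candidate Character vector of broad-cluster label(s) reclustered
#'   (a union is allowed, e.g. two biologically related clusters).
#' @slot cells Character vector of the cell ids in the candidate subset.
#' @slot grid A `data.frame` with one row per evaluated parameter set:
#'   columns `k`, `r`, `n_pcs`, `n_hvgs`, `coef`, `n_subclusters`,
#'   `admissible`.
#' @slot best Integer row index into `grid` of the winning parameter set, or
#'   `NA_integer_` when no substructure was found.
#' @slot subLabels Factor of sub-cluster labels, named by cell id; empty when
#'   `best` is `NA`.
#'
#' @seealso [reclusterOne()], [integrateLabels()]
#' @export
setClass("ReclusterResult",
    slots = c(
        candidate = "character",
        cells     = "character",
        grid      = "data.frame",
        best      = "integer",
        subLabels = "factor"
    )
)

setValidity("ReclusterResult", function(object) {
    g <- object@grid
    b <- object@best
    if (length(b) != 1L) return("best must be a single index (or NA)")
    if (!is.na(b)) {
        if (b < 1L || b > nrow(g)) return("best out of grid range")
        adm <- which(g$admissible)
        if (!(b %in% adm)) return("best must point at an admissible grid row")
        if (g$coef[b] < max(g$coef[adm]) - 1e-12)
            return("best must achieve the maximum silhouette coefficient")
        if (length(object@subLabels) != length(object@cells))
            return("subLabels must cover exactly the candidate cells")
    }
    TRUE
})

#' @describeIn ReclusterResult The winning parameter set as a one-row
#'   `data.frame`, or `NULL` when no substructure was found.
#' @param x,object A `ReclusterResult`.
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))

#' @rdname ReclusterResult
#' @export
setMethod("bestParams", "ReclusterResult", function(x) {
    if (is.na(x@best)) NULL else x@grid[x@best, , drop = FALSE]
})

#' @describeIn ReclusterResult The full parameter-grid report.
#' @export
setGeneric("gridReport", function(x) standardGeneric("gridReport"))

#' @rdname ReclusterResult
#' @export
setMethod("gridReport", "ReclusterResult", function(x) x@grid)

#' @describeIn ReclusterResult Winning sub-labels (factor named by cell id).
#' @export
setGeneric("subLabels", function(x) standardGeneric("subLabels"))

#' @rdname ReclusterResult
#' @export
setMethod("subLabels", "ReclusterResult", function(x) x@subLabels)

setMethod("show", "ReclusterResult", function(object) {
    cat(sprintf("ReclusterResult for candidate {%s}: %d cells, %d grid points\n",
                paste(object@candidate, collapse = ", "),
                length(object@cells), nrow(object@grid)))
    if (is.na(object@best)) {
        cat("  no substructure found\n")
    } else {
        b <- object@grid[object@best, ]
        cat(sprintf("  best: k=%d, r=%.2f -> %d subclusters, coef=%.3f\n",
                    b$k, b$r, b$n_subclusters, b$coef))
    }
    invisible(NULL)
})

#' Specification of a planted-structure scRNA-seq count simulation
#'
#' Describes a negative-binomial count simulation with broad clusters of
#' unequal size plus pairs of rare clusters that are transcriptionally
#' adjacent: each rare pair inherits the differential-expression (DE)
#' program of a parent broad cluster, shares a rare-specific DE program, and
#' differs only on a small private gene set. See [simulateCounts()].
#'
#' @slot nCells,nGenes Dataset dimensions.
#' @slot proportions Per-cluster cell fractions (broad clusters first, then
#'   rare clusters, in the order of `rareParents`); must sum to 1.
#' @slot deFrac Fraction of genes differentially expressed per broad cluster.
#' @slot lfcMean,lfcSd Location and scale of the absolute log2 fold-changes
#'   of DE genes (signs are random).
#' @slot nbDispersion NB dispersion phi (variance = mu + phi * mu^2).
#' @slot rareParents Integer vector: for each rare pair, the index of the
#'   broad cluster whose DE program the pair inherits.
#' @slot rareSharedFrac Fraction of genes in the rare pair's shared
#'   rare-specific DE program.
#' @slot rarePrivateGenes Number of private DE genes per rare cluster (the
#'   genes that distinguish the two members of a pair).
#' @slot rareLfcMean,rareLfcSd Location and scale of the absolute log2
#'   fold-changes of the rare-specific (shared and private) programs. Rare
#'   subtypes are defined by strong identity markers even when the subtypes
#'   are mutually similar, so this defaults higher than the broad `lfcMean`.
#' @slot baselineMeanlog,baselineSdlog Lognormal parameters of per-gene
#'   baseline mean expression.
#' @slot libSdlog Lognormal sd of per-cell library-size factors (meanlog is
#'   set so the factors have mean 1).
#' @slot seed Integer seed; the generator is deterministic given the spec.
#' @export
setClass("SimSpec",
    slots = c(
        nCells = "numeric", nGenes = "numeric",
        proportions = "numeric",
        deFrac = "numeric", lfcMean = "numeric", lfcSd = "numeric",
        nbDispersion = "numeric",
        rareParents = "integer",
        rareSharedFrac = "numeric", rarePrivateGenes = "numeric",
        rareLfcMean = "numeric", rareLfcSd = "numeric",
        baselineMeanlog = "numeric", baselineSdlog = "numeric",
        libSdlog = "numeric",
        seed = "numeric"
    )
)

setValidity("SimSpec", function(object) {
    p <- object@proportions
    if (abs(sum(p) - 1) > 1e-8) return("proportions must sum to 1")
    if (any(p <= 0)) return("all cluster proportions must be positive")
    nr <- length(object@rareParents)
    if (nr %% 2L != 0L)
        return("rareParents lists one parent per rare pair member (even length)")
    if (nr > 0) {
        rare <- utils::tail(p, nr)
        if (any(rare >= 0.05))
            return("rare cluster fractions must be below 5%")
        if (any(object@rareParents < 1 |
                object@rareParents > length(p) - nr))
            return("rareParents must index broad clusters")
    }
    if (object@nCells < length(p)) return("fewer cells than clusters")
    if (any(round(p * object@nCells) < 1))
        return("infeasible spec: a cluster would receive 0 cells")
    if (object@nbDispersion <= 0 || object@deFrac <= 0 ||
        object@lfcMean <= 0 || object@lfcSd < 0)
        return("count model parameters must be positive")
    TRUE
})

setMethod("show", "SimSpec", function(object) {
    nr <- length(object@rareParents)
    cat(sprintf("SimSpec: %d cells x %d genes, %d broad + %d rare clusters\n",
                object@nCells, object@nGenes,
                length(object@proportions) - nr, nr))
    cat(sprintf("  proportions: %s\n",
                paste(signif(object@proportions, 3), collapse = " ")))
    cat(sprintf("  deFrac=%.3g, |lfc|~N(%.2g, %.2g), phi=%.2g, seed=%d\n",
                object@deFrac, object@lfcMean, object@lfcSd,
                object@nbDispersion, as.integer(object@seed)))
    invisible(NULL)
})
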