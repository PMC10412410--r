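#' Flag heterogeneous clusters as reclustering candidates
#'
#' Clusters whose median per-cell silhouette falls below `threshold` are
#' flagged, ordered by ascending median (most heterogeneous first). The
#' semi-supervised surface: `forceInclude` adds clusters the user knows to
#' be biologically composite regardless of their score, `forceExclude`
#' removes clusters the user knows to be homogeneous or uninteresting.
#'
#' @param summary A [SilhouetteReport-class], or its per-cluster table (any
#'   data frame with columns `cluster` and `median`).
#' @param threshold Median-silhouette cutoff (default 0.25).
#' @param forceInclude,forceExclude Character vectors of cluster labels.
#' @return Character vector of candidate cluster labels, ordered by
#'   ascending median (forced inclusions keep that order; unknown forced
#'   labels are a validation error).
#' @export
flagCandidates <- function(summary, threshold = 0.25,
                           forceInclude = character(),
                           forceExclude = character()) {
    if (methods::is(summary, "SilhouetteReport"))
        summary <- as.data.frame(summary@perCluster)
    summary <- as.data.frame(summary)
    if (!nrow(summary)) stop("empty cluster summary")
    known <- as.character(summary$cluster)
    bad <- setdiff(c(forceInclude, forceExclude), known)
    if (length(bad))
        stop("validation error: unknown cluster label(s): ",
             paste(bad, collapse = ", "))
    med <- stats::setNames(summary$median, known)
    cand <- known[med < threshold]
    cand <- union(cand, forceInclude)
    cand <- setdiff(cand, forceExclude)
    cand[order(med[cand])]
}

#' Reclustering parameter grid
#'
#' Builds the Cartesian grid of SNN neighbourhood sizes and resolutions
#' swept by [reclusterOne()], with the feature-space parameters held fixed.
#' The defaults span conservative to permissive granularity.
#'
#' @param k SNN neighbourhood sizes (default `c(10, 20, 30, 50)`).
#' @param r Resolutions (default `c(0.4, 0.6, 0.8, 1.0, 1.2)`).
#' @param nPCs Principal components for the subset embedding (default 30).
#' @param nHVGs Highly variable genes re-selected within the subset
#'   (default 500). Deliberately tighter than a typical global selection:
#'   within one broad cluster only a small minority of genes is
#'   informative, and a selective local cut is what lets them drive the
#'   subset geometry.
#' @return A `data.frame` with columns `k`, `r`, `n_pcs`, `n_hvgs`.
#' @export
paramGrid <- function(k = c(10L, 20L, 30L, 50L),
                      r = c(0.4, 0.6, 0.8, 1.0, 1.2),
                      nPCs = 30L, nHVGs = 500L) {
    if (!length(k) || !length(r) || any(k <= 0) || any(r <= 0) ||
        nPCs <= 0 || nHVGs <= 0)
        stop("parameter error: grid values must be positive and non-empty")
    g <- expand.grid(k = as.integer(k), r = r, KEEP.OUT.ATTRS = FALSE)
    g$n_pcs <- as.integer(nPCs)
    g$n_hvgs <- as.integer(nHVGs)
    g
}

#' Recluster one candidate broad cluster (or union of clusters)
#'
#' The core loop. Restricted to the candidate's cells, the feature space is
#' re-derived from scratch — log-normalisation, highly variable gene
#' selection *within the subset*, and a fresh PCA — so genes that
#' distinguish closely related subpopulations but are invisible globally
#' drive the local geometry. Every grid point then builds an SNN graph and
#' runs community detection, and is scored by the overall mean per-cell
#' silhouette (cosine distance) of its sub-partition on the subset
#' embedding. The parameter set maximising that score wins; ties go to the
#' fewest subclusters, then the smallest `k` (the most conservative split).
#'
#' Grid points that produce a single community, a subcluster smaller than
#' `minSubcluster`, or have `k >= subset size` are inadmissible. If no grid
#' point is admissible the result reports "no substructure" (`best = NA`)
#' rather than an error.
#'
#' @param x A `SingleCellExperiment` with a `counts` assay, or a
#'   genes-by-cells raw count matrix.
#' @param labels Global cluster labels (factor/character named by cell id,
#'   in cell order, or a label table).
#' @param candidates Character vector of one or more cluster labels to
#'   recluster jointly (a union pools biologically related clusters).
#' @param grid Parameter grid from [paramGrid()].
#' @param seed Integer seed (applies to embedding and community detection).
#' @param minSubset Minimum candidate size (default 50); smaller is a
#'   domain error.
#' @param minSubcluster Minimum admissible subcluster size (default 5).
#' @param algorithm Community detection algorithm (default `"leiden"`).
#' @param scaleFactor,hvgMethod Normalisation / HVG options, as in
#'   [logNormalize()] and [selectHVGs()].
#' @param score `"mean"` (default) or `"median"` per-cell silhouette as the
#'   grid objective.
#' @return A [ReclusterResult-class].
#' @export
reclusterOne <- function(x, labels, candidates, grid = paramGrid(),
                         seed = 1L, minSubset = 50L, minSubcluster = 5L,
                         algorithm = c("leiden", "louvain"),
                         scaleFactor = 1e4,
                         hvgMethod = c("vst", "dispersion"),
                         score = c("mean", "median")) {
    algorithm <- match.arg(algorithm)
    hvgMethod <- match.arg(hvgMethod)
    score <- match.arg(score)
    if (!nrow(grid)) stop("parameter error: empty grid")
    counts <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else x
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
    labels <- .alignLabels(labels, colnames(counts))
    unknown <- setdiff(candidates, levels(labels))
    if (length(unknown))
        stop("validation error: unknown candidate label(s): ",
             paste(unknown, collapse = ", "))
    cells <- colnames(counts)[labels %in% candidates]
    if (length(cells) < minSubset)
        stop("candidate subset has ", length(cells), " cells; minimum is ",
             minSubset)

    sub <- counts[, cells, drop = FALSE]
    norm <- logNormalize(sub, scaleFactor = scaleFactor, dropEmpty = TRUE)
    cells <- colnames(norm)
    nsub <- length(cells)

    # local dimensionality scales with subset size: a small subset cannot
    # support as many informative components or features as the full data
    nHVGs <- min(grid$n_hvgs[1], nrow(norm), max(100L, 2L * nsub))
    hvgs <- selectHVGs(norm, nHVGs = nHVGs, method = hvgMethod)
    nPCs <- min(grid$n_pcs[1], max(5L, nsub %/% 10L), nsub - 1L,
                nHVGs - 1L)
    emb <- computeEmbedding(norm, hvgs = hvgs, nPCs = nPCs, seed = seed)

    res <- grid
    res$n_pcs <- nPCs
    res$n_hvgs <- nHVGs
    res$coef <- NA_real_
    res$n_subclusters <- NA_integer_
    res$admissible <- FALSE
    partitions <- vector("list", nrow(grid))

    for (gi in seq_len(nrow(grid))) {
        k <- grid$k[gi]
        if (k >= nsub) next
        g <- snnGraph(emb, k = k)
        lab <- suppressWarnings(
            communityDetect(g, r = grid$r[gi], seed = seed,
                            algorithm = algorithm))
        ncl <- nlevels(droplevels(lab))
        res$n_subclusters[gi] <- ncl
        if (ncl < 2) next                        # no split at this point
        if (min(table(droplevels(lab))) < minSubcluster) next
        rep <- silhouetteSamples(emb, lab, cap = .Machine$integer.max)
        s <- rep@perCell$s
        res$coef[gi] <- if (score == "mean") mean(s) else stats::median(s)
        res$admissible[gi] <- TRUE
        partitions[[gi]] <- lab
    }

    adm <- which(res$admissible)
    if (!length(adm)) {
        best <- NA_integer_
        sub_labels <- factor(character())
    } else {
        o <- adm[order(-res$coef[adm], res$n_subclusters[adm], res$k[adm])]
        best <- o[1]
        sub_labels <- droplevels(partitions[[best]])
    }
    methods::new("ReclusterResult",
                 candidate = as.character(candidates),
                 cells = cells, grid = res, best = best,
                 subLabels = sub_labels)
}

#' Integrate reclustering results back into the global labelling
#'
#' Cells belonging to a reclustered candidate receive hierarchical labels
#' `"<parent>.<sub>"` (for a union candidate, the parent labels joined by
#' `"+"`); every other cell keeps its original label bit-identically — the
#' guarantee that reclustering one cluster cannot overcluster the rest.
#' Results whose `best` is `NA` (no substructure) leave their cells
#' untouched. Candidates of different results must be disjoint.
#'
#' @param global Global labels (factor/character named by cell id, in cell
#'   order, or a label table) — pass the same object the results were
#'   derived from.
#' @param results A list of [ReclusterResult-class] objects (or a single
#'   one).
#' @return A factor of final labels named by cell id, same cells and order
#'   as `global`.
#' @export
integrateLabels <- function(global, results) {
    if (methods::is(results, "ReclusterResult")) results <- list(results)
    if (is.data.frame(global))
        global <- stats::setNames(as.character(global$label),
                                  as.character(global$cell_id))
    nms <- names(global)
    if (is.null(nms)) stop("global labels must be named by cell id")
    out <- as.character(global)
    names(out) <- nms

    claimed <- character()
    for (resu in results) {
        ol <- intersect(resu@candidate, claimed)
        if (length(ol))
            stop("validation error: overlapping candidates: ",
                 paste(ol, collapse = ", "))
        claimed <- c(claimed, resu@candidate)
        if (is.na(resu@best)) next
        parent <- paste(resu@candidate, collapse = "+")
        sl <- resu@subLabels
        miss <- setdiff(names(sl), nms)
        if (length(miss))
            stop("sub-labelled cells not present in global labels")
        out[names(sl)] <- paste0(parent, ".", as.character(sl))
    }
    factor(out)
}
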