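#' Construct a simulation specification
#'
#' Builds a validated [SimSpec-class]. The default describes the rare-pair
#' benchmark geometry: 1000 cells by 2000 genes in seven clusters — five
#' broad clusters of 18.8% each and one rare pair of 3% each. The rare pair
#' inherits the full DE program of broad cluster 1 (its "parent", which
#' places the pair near that cluster in expression space), shares a
#' rare-specific DE program, and each member carries a small private DE set
#' — so the two rare clusters sit adjacent in the embedding, are merged by
#' a conservative clustering pass, and are separable only once features are
#' re-selected locally.
#'
#' Of each rare cluster's own (non-parental) DE genes, the shared program
#' makes up `rareSharedFrac * nGenes` of them against
#' `rarePrivateGenes` private ones — with the defaults, 40 shared versus 20
#' private; counting the inherited parent program, well over 80% of each
#' rare cluster's DE program is shared within the pair. The
#' rare programs use their own effect-size distribution
#' (`rareLfcMean`/`rareLfcSd`), stronger than the broad programs: rare
#' subtypes are defined by strong identity markers even when mutually
#' similar.
#'
#' @inheritParams SimSpec-class
#' @param proportions Per-cluster fractions, broad clusters first; rare
#'   clusters (one pair per two entries of `rareParents`) last.
#' @param rareParents Integer vector, one entry per rare cluster, giving
#'   the parent broad cluster (default `c(1, 1)`: one pair under cluster 1).
#' @return A [SimSpec-class].
#' @export
simSpec <- function(nCells = 1000, nGenes = 2000,
                    proportions = c(rep(0.188, 5), 0.03, 0.03),
                    deFrac = 0.10, lfcMean = 1.2, lfcSd = 0.3,
                    nbDispersion = 0.5,
                    rareParents = c(1L, 1L),
                    rareSharedFrac = 0.02, rarePrivateGenes = 20,
                    rareLfcMean = 2.0, rareLfcSd = 0.3,
                    baselineMeanlog = -1, baselineSdlog = 1.5,
                    libSdlog = 0.35, seed = 1L) {
    methods::new("SimSpec",
        nCells = nCells, nGenes = nGenes, proportions = proportions,
        deFrac = deFrac, lfcMean = lfcMean, lfcSd = lfcSd,
        nbDispersion = nbDispersion, rareParents = as.integer(rareParents),
        rareSharedFrac = rareSharedFrac,
        rarePrivateGenes = rarePrivateGenes,
        rareLfcMean = rareLfcMean, rareLfcSd = rareLfcSd,
        baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
        libSdlog = libSdlog, seed = seed)
}

#' Read a simulation specification from YAML
#'
#' Reads a YAML file whose keys are the arguments of [simSpec()]. The
#' shipped default spec is available as
#' `system.file("extdata", "rare_pair_benchmark.yaml", package = "scRecluster")`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A [SimSpec-class].
#' @export
readSimSpec <- function(path, seed = NULL) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simSpec))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("validation error: unknown SimSpec key(s): ",
             paste(bad, collapse = ", "))
    if (!is.null(seed)) vals$seed <- seed
    do.call(simSpec, vals)
}

#' Simulate counts with planted broad and rare cluster structure
#'
#' Draws a negative-binomial count matrix under `spec`. Per-gene baseline
#' means are lognormal; each cluster multiplies its DE genes' means by
#' `2^lfc` with `|lfc| ~ N(lfcMean, lfcSd)` and random sign; rare clusters
#' inherit their parent's DE program, add the pair-shared rare program and
#' their own private genes. Counts are
#' `NB(mean = baseline * 2^lfc * libFactor, dispersion = phi)` with
#' lognormal per-cell library factors. Deterministic given `spec@seed`.
#'
#' @param spec A [SimSpec-class].
#' @return A `SingleCellExperiment` with assay `counts`,
#'   `colData$true_label` (factor: `B1..Bn` broad, `R1..Rm` rare),
#'   `rowData` holding the per-cluster log2 fold-change matrix, and
#'   `metadata(sce)$markers` — per-cluster lists of planted DE genes, with
#'   `private` sets for rare clusters (their exclusive markers).
#' @export
simulateCounts <- function(spec) {
    methods::validObject(spec)
    set.seed(as.integer(spec@seed) %% .Machine$integer.max)
    nG <- as.integer(spec@nGenes); nC <- as.integer(spec@nCells)
    nRare <- length(spec@rareParents)
    nBroad <- length(spec@proportions) - nRare
    K <- nBroad + nRare
    labs <- c(if (nBroad) paste0("B", seq_len(nBroad)),
              if (nRare) paste0("R", seq_len(nRare)))

    sizes <- .apportion(spec@proportions, nC)
    truth <- factor(rep(labs, sizes), levels = labs)
    gene_ids <- sprintf("gene%04d", seq_len(nG))
    cell_ids <- sprintf("cell%04d", seq_len(nC))

    baseline <- stats::rlnorm(nG, spec@baselineMeanlog, spec@baselineSdlog)
    lfc <- matrix(0, nG, K, dimnames = list(gene_ids, labs))
    drawLfc <- function(n, mean = spec@lfcMean, sd = spec@lfcSd)
        sample(c(-1, 1), n, replace = TRUE) *
            pmax(stats::rnorm(n, mean, sd), 0.1)

    nDE <- max(1L, round(spec@deFrac * nG))
    markers <- list()
    if (K > 1) {                 # a single cluster has nothing to differ from
        for (b in seq_len(nBroad)) {
            genes <- sample.int(nG, nDE)
            lfc[genes, b] <- drawLfc(nDE)
            markers[[labs[b]]] <- list(de = gene_ids[genes])
        }
    }
    if (nRare) {
        nShared <- max(1L, round(spec@rareSharedFrac * nG))
        nPriv <- max(1L, round(spec@rarePrivateGenes))
        for (pair in seq_len(nRare / 2L)) {
            r1 <- nBroad + 2L * pair - 1L
            r2 <- r1 + 1L
            parent <- spec@rareParents[2L * pair - 1L]
            # inherit the parent's program -> the pair sits near the parent
            lfc[, r1] <- lfc[, parent]
            lfc[, r2] <- lfc[, parent]
            # identity markers of real subtypes are robustly expressed
            # genes; plant the rare programs on the upper half of baseline
            # expression so they are detectable at realistic depth
            pool <- which(lfc[, parent] == 0 &
                          baseline > stats::median(baseline))
            pick <- sample(pool, nShared + 2L * nPriv)
            shared <- pick[seq_len(nShared)]
            p1 <- pick[nShared + seq_len(nPriv)]
            p2 <- pick[nShared + nPriv + seq_len(nPriv)]
            sl <- drawLfc(nShared, spec@rareLfcMean, spec@rareLfcSd)
            lfc[shared, r1] <- sl
            lfc[shared, r2] <- sl
            # private markers: up only, at the rare-program effect size
            lfc[p1, r1] <- abs(drawLfc(nPriv, spec@rareLfcMean,
                                       spec@rareLfcSd))
            lfc[p2, r2] <- abs(drawLfc(nPriv, spec@rareLfcMean,
                                       spec@rareLfcSd))
            markers[[labs[r1]]] <- list(de = gene_ids[c(shared, p1)],
                                        private = gene_ids[p1])
            markers[[labs[r2]]] <- list(de = gene_ids[c(shared, p2)],
                                        private = gene_ids[p2])
        }
    }

    libf <- stats::rlnorm(nC, -spec@libSdlog^2 / 2, spec@libSdlog)
    size <- 1 / spec@nbDispersion
    counts <- matrix(0L, nG, nC, dimnames = list(gene_ids, cell_ids))
    for (ci in seq_len(K)) {
        cells <- which(truth == labs[ci])
        mu_g <- baseline * 2^lfc[, ci]
        mu <- outer(mu_g, libf[cells])
        counts[, cells] <- stats::rnbinom(length(mu), mu = mu, size = size)
    }

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(
            Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")))
    SummarizedExperiment::colData(sce)$true_label <- truth
    SummarizedExperiment::rowData(sce)$lfc <- lfc
    S4Vectors::metadata(sce)$markers <- markers
    S4Vectors::metadata(sce)$spec <- spec
    sce
}

# Integer cluster sizes from fractions, largest-remainder rounding.
.apportion <- function(p, n) {
    raw <- p * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement, computed from the contingency
#' table; invariant to label permutations; 1 for identical partitions, and
#' near 0 for independent ones.
#'
#' @param truth,pred Label vectors of equal length (any atomic/factor type).
#' @return A single number `<= 1`.
#' @export
adjustedRandIndex <- function(truth, pred) {
    if (length(truth) != length(pred))
        stop("labelings must have equal length")
    tab <- table(truth, pred)
    n <- sum(tab)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    expected <- si * sj / choose(n, 2)
    mx <- (si + sj) / 2
    if (mx == expected) return(1)   # both partitions trivial
    (sij - expected) / (mx - expected)
}

#' Normalised mutual information between two labelings
#'
#' Mutual information normalised by the geometric mean of the two label
#' entropies, `I(truth; pred) / sqrt(H(truth) H(pred))`; in `[0, 1]`, with
#' 1 for identical partitions and 0 when either labeling is constant (or
#' the two are independent).
#'
#' @inheritParams adjustedRandIndex
#' @return A single number in `[0, 1]`.
#' @export
normalizedMutualInfo <- function(truth, pred) {
    if (length(truth) != length(pred))
        stop("labelings must have equal length")
    p <- table(truth, pred) / length(truth)
    pr <- rowSums(p); pc <- colSums(p)
    ht <- -sum(pr[pr > 0] * log(pr[pr > 0]))
    hp <- -sum(pc[pc > 0] * log(pc[pc > 0]))
    if (ht == 0 || hp == 0) return(0)
    e <- outer(pr, pc)
    nz <- p > 0
    mi <- sum(p[nz] * log(p[nz] / e[nz]))
    min(max(mi / sqrt(ht * hp), 0), 1)
}

#' Benchmark clustering methods on a simulated dataset
#'
#' Runs a set of clustering methods over seeded replicates of a simulation
#' and tabulates their agreement with ground truth. The baselines are thin
#' adapters around standard algorithms operating on the same preprocessed
#' embedding: `single_pass_louvain` is one conservative SNN/Louvain pass
#' (the broad pass alone), `kmeans` and `hierarchical` (Ward linkage) are
#' given the true number of clusters, and `dbscan` is a minimal
#' density-based baseline with its radius set to the median 5-NN distance.
#' The full iterative method itself enters as `recluster`, i.e.
#' [runPipeline()] with `config`.
#'
#' @param spec A [SimSpec-class]; its seed is replaced by each element of
#'   `seeds`.
#' @param methods Subset of `c("recluster", "single_pass_louvain", "kmeans",
#'   "hierarchical", "dbscan")`.
#' @param seeds Integer vector of simulation/clustering seeds.
#' @param config Pipeline configuration (see [defaultConfig()]) used for
#'   `recluster` and for the broad pass.
#' @return A `data.frame` with one row per seed-method pair: `seed`,
#'   `method`, `k` (clusters found), `ari`, `nmi`, `mean_silhouette`.
#' @export
runBenchmark <- function(spec,
                         methods = c("recluster", "single_pass_louvain",
                                     "kmeans", "hierarchical", "dbscan"),
                         seeds = 1:5, config = defaultConfig()) {
    allowed <- c("recluster", "single_pass_louvain", "kmeans",
                 "hierarchical", "dbscan")
    bad <- setdiff(methods, allowed)
    if (length(bad))
        stop("parameter error: unknown method(s): ",
             paste(bad, collapse = ", "))
    rows <- list()
    for (sd in seeds) {
        spec@seed <- sd
        sce <- simulateCounts(spec)
        truth <- SummarizedExperiment::colData(sce)$true_label
        trueK <- nlevels(truth)
        pp <- config$preprocess
        sce <- logNormalize(sce, scaleFactor = pp$scale_factor)
        hv <- selectHVGs(sce, nHVGs = min(pp$n_hvgs, nrow(sce)),
                         method = pp$hvg_method)
        sce <- computeEmbedding(sce, hvgs = hv, nPCs = pp$n_pcs, seed = sd)
        emb <- SingleCellExperiment::reducedDim(sce, "PCA")
        for (m in methods) {
            pred <- switch(m,
                recluster = {
                    cfg <- config; cfg$seed <- sd
                    runPipeline(sce, cfg)$labels
                },
                single_pass_louvain = {
                    g <- snnGraph(emb, k = config$initial$k,
                                  prune = config$initial$prune)
                    communityDetect(g, r = config$initial$r, seed = sd,
                                    algorithm = "louvain")
                },
                kmeans = {
                    set.seed(sd)
                    factor(stats::kmeans(emb, centers = trueK,
                                         nstart = 10)$cluster)
                },
                hierarchical = factor(stats::cutree(
                    stats::hclust(stats::dist(emb), method = "ward.D2"),
                    k = trueK)),
                dbscan = factor(.dbscanLabels(emb)))
            k <- nlevels(droplevels(factor(as.character(pred))))
            msil <- if (k >= 2)
                mean(silhouetteSamples(emb, as.character(pred))@perCell$s)
            else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
                seed = sd, method = m, k = k,
                ari = adjustedRandIndex(truth, pred),
                nmi = normalizedMutualInfo(truth, pred),
                mean_silhouette = msil)
        }
    }
    do.call(rbind, rows)
}

# Minimal DBSCAN on a Euclidean distance matrix (no package in the stack
# provides one). eps defaults to the median 5-NN distance; noise points get
# the label "noise".
.dbscanLabels <- function(emb, eps = NULL, minPts = 5L) {
    d <- as.matrix(stats::dist(emb))
    n <- nrow(d)
    if (is.null(eps))
        eps <- stats::median(apply(d, 1, function(v) sort(v)[minPts + 1L]))
    nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
    core <- vapply(nb, length, integer(1)) >= minPts
    lab <- rep(NA_integer_, n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (!is.na(lab[i]) || !core[i]) next
        cl <- cl + 1L
        queue <- i
        lab[i] <- cl
        while (length(queue)) {
            j <- queue[[1]]; queue <- queue[-1]
            for (q in nb[[j]]) {
                if (is.na(lab[q])) {
                    lab[q] <- cl
                    if (core[q]) queue <- c(queue, q)
                }
            }
        }
    }
    ifelse(is.na(lab), "noise", as.character(lab))
}
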