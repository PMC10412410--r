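#' Default pipeline configuration
#'
#' The full configuration tree with every tunable materialised, so a run
#' manifest is never ambiguous about what was used. Top-level keys:
#' `preprocess` (`scale_factor`, `n_hvgs`, `hvg_method`, `n_pcs`,
#' `distance_space`), `initial` (`k`, `r`, `algorithm`, `prune` — the
#' conservative broad pass), `recluster` (`threshold`, `grid` with `k` and
#' `r` vectors, `n_pcs` and `n_hvgs` for the local feature space,
#' `force_include`, `force_exclude`, `max_depth`, `min_subset`,
#' `min_subcluster`, `score`, `accept_coef`), and `seed`.
#'
#' @return A nested named list.
#' @export
defaultConfig <- function() {
    list(
        preprocess = list(
            scale_factor = 1e4,
            n_hvgs = 2000L,
            hvg_method = "vst",
            n_pcs = 30L,
            distance_space = "pca"
        ),
        initial = list(
            k = 20L,
            r = 0.3,
            algorithm = "leiden",
            prune = 1 / 15
        ),
        recluster = list(
            threshold = 0.25,
            grid = list(k = c(10L, 20L, 30L, 50L),
                        r = c(0.4, 0.6, 0.8, 1.0, 1.2)),
            n_pcs = 30L,
            n_hvgs = 500L,
            force_include = character(),
            force_exclude = character(),
            max_depth = 2L,
            min_subset = 50L,
            min_subcluster = 5L,
            score = "mean",
            accept_coef = 0.1
        ),
        seed = 1L
    )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, overlays it on [defaultConfig()] and
#' validates it en bloc before any computation: unknown keys anywhere in
#' the tree are rejected by name, as are out-of-range values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list merged on top (flags win over file).
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = NULL) {
    cfg <- defaultConfig()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        cfg <- .mergeConfig(cfg, user, "")
    }
    if (!is.null(overrides)) cfg <- .mergeConfig(cfg, overrides, "")
    validateConfig(cfg)
    cfg
}

.mergeConfig <- function(base, user, prefix) {
    if (is.null(user)) return(base)
    if (!is.list(user))
        stop("validation error: expected a mapping at '", prefix, "'")
    for (key in names(user)) {
        full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
        if (!key %in% names(base))
            stop("validation error: unknown config key '", full, "'")
        if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
            !identical(key, "grid")) {
            base[[key]] <- .mergeConfig(base[[key]], user[[key]], full)
        } else if (identical(key, "grid")) {
            base[[key]] <- .mergeConfig(base[[key]], user[[key]], full)
        } else {
            base[[key]] <- user[[key]]
        }
    }
    base
}

#' @rdname readRunConfig
#' @param config A configuration list to validate.
#' @export
validateConfig <- function(config) {
    pp <- config$preprocess; ini <- config$initial; rc <- config$recluster
    fail <- function(key, why)
        stop("validation error: config key '", key, "' ", why)
    if (pp$scale_factor <= 0) fail("preprocess.scale_factor",
                                   "must be positive")
    if (pp$n_hvgs <= 0) fail("preprocess.n_hvgs", "must be positive")
    if (!pp$hvg_method %in% c("vst", "dispersion"))
        fail("preprocess.hvg_method", "must be 'vst' or 'dispersion'")
    if (pp$n_pcs < 2) fail("preprocess.n_pcs", "must be at least 2")
    if (!pp$distance_space %in% c("pca", "hvg_lognorm"))
        fail("preprocess.distance_space", "must be 'pca' or 'hvg_lognorm'")
    if (ini$k < 2) fail("initial.k", "must be at least 2")
    if (ini$r <= 0) fail("initial.r", "must be positive")
    if (!ini$algorithm %in% c("leiden", "louvain"))
        fail("initial.algorithm", "must be 'leiden' or 'louvain'")
    if (ini$prune < 0 || ini$prune >= 1) fail("initial.prune",
                                              "must be in [0, 1)")
    if (!length(rc$grid$k) || !length(rc$grid$r))
        fail("recluster.grid", "must list k and r values")
    if (any(rc$grid$k <= 0) || any(rc$grid$r <= 0))
        fail("recluster.grid", "values must be positive")
    if (rc$max_depth < 1) fail("recluster.max_depth", "must be at least 1")
    if (rc$min_subset < 2) fail("recluster.min_subset", "must be at least 2")
    if (rc$min_subcluster < 1) fail("recluster.min_subcluster",
                                    "must be at least 1")
    if (!rc$score %in% c("mean", "median"))
        fail("recluster.score", "must be 'mean' or 'median'")
    if (rc$n_pcs < 2) fail("recluster.n_pcs", "must be at least 2")
    if (rc$n_hvgs < 2) fail("recluster.n_hvgs", "must be at least 2")
    if (!is.numeric(rc$accept_coef))
        fail("recluster.accept_coef", "must be numeric")
    invisible(config)
}

#' Run the full silhouette-guided reclustering pipeline
#'
#' End to end: log-normalisation, global HVG selection and PCA; a
#' conservative broad clustering pass; cosine-silhouette heterogeneity
#' estimation; flagging of heterogeneous clusters (semi-supervised via the
#' config's `force_include`/`force_exclude`); per-candidate reclustering
#' with locally re-selected features over a parameter grid scored by
#' silhouette coefficient; and integration of the winning sub-labels back
#' into the global labelling — non-candidate cells keep their labels
#' bit-identically. Reclustering rounds repeat on newly created subclusters
#' up to `recluster.max_depth`. Candidates that turn out smaller than
#' `min_subset`, or in which no grid point finds substructure, are left
#' unchanged (and not retried).
#'
#' A winning sub-partition is integrated only when its own silhouette
#' coefficient exceeds `recluster.accept_coef` (default 0.1): modularity
#' optimisation will split almost any cluster if asked, but a split of a
#' genuinely homogeneous cluster is a partition of noise and scores a
#' near-zero local silhouette coefficient, while real substructure — once
#' the subset's own features are selected — scores well clear of it. This
#' is the guard that lets flagging be permissive without overclustering
#' homogeneous populations; set `accept_coef = -Inf` to integrate every
#' winning split.
#'
#' If the broad pass yields a single cluster the pipeline reports "nothing
#' to do" and returns the broad labels.
#'
#' @param x A `SingleCellExperiment` with a `counts` assay (a `logcounts`
#'   assay and `"PCA"` reduced dimension are reused if already present), or
#'   a genes-by-cells raw count matrix.
#' @param config Configuration from [defaultConfig()] / [readRunConfig()].
#' @return A list with elements `labels` (final factor, named by cell id),
#'   `broad` (broad-pass labels), `silhouette` (the broad-pass
#'   [SilhouetteReport-class]; `NULL` for a single-cluster broad pass),
#'   `candidates` (flagged labels per round), `recluster` (list of
#'   [ReclusterResult-class]), and `manifest` (config echo, seed, stage
#'   log).
#' @export
runPipeline <- function(x, config = defaultConfig()) {
    validateConfig(config)
    seed <- as.integer(config$seed)
    log <- character()
    note <- function(...) {
        msg <- sprintf(...)
        log[[length(log) + 1L]] <<- msg
        message("[pipeline] ", msg)
    }

    pp <- config$preprocess
    if (methods::is(x, "SummarizedExperiment")) {
        sce <- x
        if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
            note("normalising counts (scale factor %g)", pp$scale_factor)
            sce <- logNormalize(sce, scaleFactor = pp$scale_factor)
        }
        if (!"PCA" %in% SingleCellExperiment::reducedDimNames(sce)) {
            note("selecting %d HVGs (%s) and computing %d PCs",
                 min(pp$n_hvgs, nrow(sce)), pp$hvg_method, pp$n_pcs)
            hv <- selectHVGs(sce, nHVGs = min(pp$n_hvgs, nrow(sce)),
                             method = pp$hvg_method)
            sce <- computeEmbedding(sce, hvgs = hv, nPCs = pp$n_pcs,
                                    seed = seed)
        }
        counts <- SummarizedExperiment::assay(sce, "counts")
        norm <- SummarizedExperiment::assay(sce, "logcounts")
        emb <- SingleCellExperiment::reducedDim(sce, "PCA")
    } else {
        counts <- x
        if (is.null(colnames(counts)))
            colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
        note("normalising counts (scale factor %g)", pp$scale_factor)
        norm <- logNormalize(counts, scaleFactor = pp$scale_factor)
        counts <- counts[, colnames(norm), drop = FALSE]
        note("selecting %d HVGs (%s) and computing %d PCs",
             min(pp$n_hvgs, nrow(norm)), pp$hvg_method, pp$n_pcs)
        hv <- selectHVGs(norm, nHVGs = min(pp$n_hvgs, nrow(norm)),
                         method = pp$hvg_method)
        emb <- computeEmbedding(norm, hvgs = hv, nPCs = pp$n_pcs,
                                seed = seed)
    }
    if (identical(pp$distance_space, "hvg_lognorm"))
        silspace <- t(as.matrix(norm[rownames(norm) %in%
            selectHVGs(norm, nHVGs = min(pp$n_hvgs, nrow(norm)),
                       method = pp$hvg_method)$gene_id, , drop = FALSE]))
    else silspace <- emb

    ini <- config$initial
    note("broad pass: SNN k=%d, %s at r=%.2f", ini$k, ini$algorithm, ini$r)
    g <- snnGraph(emb, k = ini$k, prune = ini$prune)
    broad <- communityDetect(g, r = ini$r, seed = seed,
                             algorithm = ini$algorithm)
    note("broad pass found %d clusters", nlevels(broad))

    if (nlevels(broad) < 2) {
        note("single broad cluster: nothing to do")
        return(list(labels = broad, broad = broad, silhouette = NULL,
                    candidates = list(), recluster = list(),
                    manifest = list(config = config, seed = seed,
                                    log = log)))
    }

    rc <- config$recluster
    grid <- paramGrid(k = rc$grid$k, r = rc$grid$r,
                      nPCs = rc$n_pcs, nHVGs = rc$n_hvgs)
    labels <- broad
    results <- list()
    cand_log <- list()
    exhausted <- character()
    firstReport <- NULL
    newly <- levels(broad)

    for (depth in seq_len(rc$max_depth)) {
        rep <- silhouetteSamples(silspace, labels, seed = seed)
        if (is.null(firstReport)) firstReport <- rep
        if (depth == 1L) {
            cand <- flagCandidates(rep, threshold = rc$threshold,
                                   forceInclude = rc$force_include,
                                   forceExclude = rc$force_exclude)
        } else {
            # subclusters born in the previous round are candidates by
            # construction: their substructure was invisible in the global
            # embedding, so only a fresh local pass can rule it out; the
            # accept_coef rule discards null splits
            cand <- setdiff(newly, rc$force_exclude)
        }
        cand <- setdiff(cand, exhausted)
        cand_log[[depth]] <- cand
        if (!length(cand)) {
            note("round %d: no reclustering candidates", depth)
            break
        }
        note("round %d: %d candidate(s): %s", depth, length(cand),
             paste(cand, collapse = ", "))
        newly <- character()
        for (cl in cand) {
            exhausted <- c(exhausted, cl)
            sz <- sum(labels == cl)
            if (sz < rc$min_subset) {
                note("skipping %s: %d cells < min_subset %d", cl, sz,
                     rc$min_subset)
                next
            }
            resu <- reclusterOne(counts, labels, cl, grid = grid,
                                 seed = seed, minSubset = rc$min_subset,
                                 minSubcluster = rc$min_subcluster,
                                 algorithm = ini$algorithm,
                                 scaleFactor = pp$scale_factor,
                                 hvgMethod = pp$hvg_method,
                                 score = rc$score)
            results[[length(results) + 1L]] <- resu
            if (is.na(resu@best)) {
                note("%s: no substructure", cl)
                next
            }
            b <- resu@grid[resu@best, ]
            if (b$coef <= rc$accept_coef) {
                # the optimal sub-partition is itself incoherent: treat as
                # spurious substructure and leave the cluster intact
                note(paste0("%s: best split rejected (coef %.3f <= ",
                            "accept_coef %.2f)"), cl, b$coef,
                     rc$accept_coef)
                next
            }
            note("%s: best k=%d r=%.2f -> %d subclusters (coef %.3f)",
                 cl, b$k, b$r, b$n_subclusters, b$coef)
            labels <- integrateLabels(labels, resu)
            labels <- labels[names(broad)]
            newly <- c(newly,
                       paste0(cl, ".", levels(droplevels(resu@subLabels))))
        }
        if (!length(newly)) break
    }

    list(labels = labels, broad = broad, silhouette = firstReport,
         candidates = cand_log, recluster = results,
         manifest = list(config = config, seed = seed, log = log))
}
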