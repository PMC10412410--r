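test_that("the generator is deterministic and the spec validates", {
    spec <- simSpec(nCells = 200, nGenes = 150, seed = 5)
    s1 <- simulateCounts(spec)
    s2 <- simulateCounts(spec)
    expect_identical(as.matrix(SummarizedExperiment::assay(s1)),
                     as.matrix(SummarizedExperiment::assay(s2)))
    expect_identical(s1$true_label, s2$true_label)

    expect_error(simSpec(proportions = c(0.5, 0.4)), "sum to 1")
    expect_error(simSpec(proportions = c(0.4, 0.5, 0.05, 0.05)),
                 "below 5%")   # rare fraction at 5%
    expect_error(simSpec(nCells = 1000,
                         proportions = c(rep(0.9995 / 5, 5), 0.0003,
                                         0.0002)),
                 "0 cells")
    expect_error(simSpec(nbDispersion = 0), "positive")
})

test_that("cluster sizes follow the spec proportions", {
    sce <- simulateCounts(simSpec(seed = 3))
    tab <- table(sce$true_label)
    expect_identical(as.integer(tab),
                     c(rep(188L, 5), 30L, 30L))
    expect_identical(dim(sce), c(2000L, 1000L))
})

test_that("a one-cluster spec has no differential structure", {
    sce <- simulateCounts(simSpec(nCells = 150, nGenes = 100,
                                  proportions = 1,
                                  rareParents = integer(), seed = 2))
    expect_identical(nlevels(sce$true_label), 1L)
    expect_true(all(SummarizedExperiment::rowData(sce)$lfc == 0))
})

test_that("simulated count marginals match the NB moments", {
    # one cluster, no library-size spread: every gene is NB(mu, phi)
    spec <- simSpec(nCells = 10000, nGenes = 60, proportions = 1,
                    rareParents = integer(), nbDispersion = 0.5,
                    libSdlog = 1e-8, seed = 10)
    sce <- simulateCounts(spec)
    cnt <- as.matrix(SummarizedExperiment::assay(sce))
    mu <- rowMeans(cnt)
    v <- apply(cnt, 1, var)
    expected <- mu + 0.5 * mu^2
    keep <- mu > 0.5
    # variance within sampling error of the NB relation, gene by gene
    relerr <- abs(v[keep] - expected[keep]) / expected[keep]
    expect_lt(median(relerr), 0.10)
    expect_lt(mean(relerr > 0.35), 0.05)
})

test_that("rare pair centroids are mutually closer than to any broad
           cluster", {
    hits <- 0L
    for (sd in 1:10) {
        spec <- readSimSpec(system.file("extdata", "rare_pair_benchmark.yaml",
                                        package = "scRecluster"), seed = sd)
        sce <- simulateCounts(spec)
        sce <- logNormalize(sce)
        hv <- selectHVGs(sce, nHVGs = 2000)
        sce <- computeEmbedding(sce, hv, nPCs = 30, seed = sd)
        emb <- SingleCellExperiment::reducedDim(sce, "PCA")
        truth <- sce$true_label
        cent <- vapply(levels(truth), function(l)
            colMeans(emb[truth == l, , drop = FALSE]),
            numeric(ncol(emb)))
        d <- as.matrix(dist(t(cent)))
        broad <- paste0("B", 1:5)
        if (d["R1", "R2"] < min(d["R1", broad], d["R2", broad]))
            hits <- hits + 1L
    }
    expect_gte(hits, 9L)
})

test_that("ARI matches its definition and an established implementation", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    # invariance to label permutation
    expect_equal(adjustedRandIndex(c("a", "a", "b", "b"),
                                   c("x", "x", "y", "y")), 1)
    # hand-derived from the contingency formula: all nij = 1 so the index
    # term is 0 and ARI = -expected / (max - expected) = -0.5
    expect_equal(adjustedRandIndex(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
    expect_error(adjustedRandIndex(1:3, 1:4), "equal length")

    skip_if_not_installed("mclust")
    set.seed(123)
    for (i in 1:100) {
        n <- sample(10:60, 1)
        t <- sample(1:4, n, replace = TRUE)
        p <- sample(1:5, n, replace = TRUE)
        expect_equal(adjustedRandIndex(t, p),
                     mclust::adjustedRandIndex(t, p), tolerance = 1e-10)
    }
})

test_that("NMI matches its entropy definition on hand-checked cases", {
    expect_equal(normalizedMutualInfo(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
    expect_equal(normalizedMutualInfo(c(1, 2, 1, 2), c(3, 3, 3, 3)), 0)
    # independent partitions of 4 cells: joint is uniform, MI = 0
    expect_equal(normalizedMutualInfo(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
    # 3/1 vs 2/2 split: I = sum p log(p/(pq)) with p = (2/4, 1/4, 1/4)
    t <- c("a", "a", "a", "b"); p <- c("x", "x", "y", "y")
    mi <- 2/4 * log((2/4) / (3/4 * 2/4)) + 1/4 * log((1/4) / (3/4 * 2/4)) +
          1/4 * log((1/4) / (1/4 * 2/4))
    ht <- -(3/4 * log(3/4) + 1/4 * log(1/4)); hp <- log(2)
    expect_equal(normalizedMutualInfo(t, p), mi / sqrt(ht * hp),
                 tolerance = 1e-12)
})

test_that("ARI and NMI agree with scikit-learn on random label pairs", {
    py <- Sys.which("python")
    skip_if(py == "", "no python interpreter on PATH")
    set.seed(99)
    rows <- do.call(rbind, lapply(1:100, function(i) {
        n <- sample(8:40, 1)
        data.frame(i = i, t = sample(1:4, n, TRUE), p = sample(1:4, n, TRUE))
    }))
    inp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    write.csv(rows, inp, row.names = FALSE)
    code <- paste0(
        "import sys, pandas as pd\n",
        "from sklearn.metrics import adjusted_rand_score as ari,",
        " normalized_mutual_info_score as nmi\n",
        "d = pd.read_csv(sys.argv[1])\n",
        "res = d.groupby('i').apply(lambda g: pd.Series(",
        "{'ari': ari(g.t, g.p),",
        " 'nmi': nmi(g.t, g.p, average_method='geometric')}),",
        " include_groups=False)\n",
        "res.to_csv(sys.argv[2])\n")
    status <- system2(py, c("-", inp, out), input = code,
                      stdout = FALSE, stderr = FALSE)
    skip_if(status != 0, "scikit-learn unavailable")
    ref <- read.csv(out)
    for (i in seq_len(nrow(ref))) {
        g <- rows[rows$i == ref$i[i], ]
        expect_equal(adjustedRandIndex(g$t, g$p), ref$ari[i],
                     tolerance = 1e-10)
        expect_equal(normalizedMutualInfo(g$t, g$p), ref$nmi[i],
                     tolerance = 1e-10)
    }
})

test_that("the benchmark table has one row per seed-method pair", {
    spec <- simSpec(nCells = 240, nGenes = 200,
                    proportions = c(0.5, 0.5), rareParents = integer(),
                    lfcMean = 2, deFrac = 0.2, seed = 1)
    tab <- runBenchmark(spec, methods = "kmeans", seeds = 7L)
    expect_identical(nrow(tab), 1L)
    expect_identical(tab$method, "kmeans")
    expect_equal(tab$ari, 1, tolerance = 0.05)
    expect_error(runBenchmark(spec, methods = "magic", seeds = 1),
                 "unknown method")
})

test_that("well-separated data is easy for every baseline", {
    spec <- simSpec(nCells = 300, nGenes = 300,
                    proportions = c(0.5, 0.3, 0.2),
                    rareParents = integer(),
                    lfcMean = 2.5, deFrac = 0.3, seed = 4)
    tab <- runBenchmark(spec,
                        methods = c("single_pass_louvain", "kmeans",
                                    "hierarchical"),
                        seeds = 4L)
    expect_true(all(tab$ari > 0.95))
    expect_true(all(tab$nmi > 0.9))
})
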