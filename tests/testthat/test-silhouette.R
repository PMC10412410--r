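test_that("cosine distance hits its geometric anchors", {
    expect_equal(cosineDistance(c(1, 2, 3), c(2, 4, 6)), 0)
    expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
    expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
    expect_error(cosineDistance(c(0, 0), c(1, 1)), "zero")
    expect_error(cosineDistance(1:3, 1:4), "equal length")
})

test_that("pairwise cosine matrix matches the elementwise loop oracle", {
    set.seed(42)
    x <- matrix(rnorm(3 * 5), 3, 5)
    expect_equal(unname(cosineDistanceMatrix(x)), oracleCosMatrix(x),
                 tolerance = 1e-12)
    # blockwise evaluation is exact regardless of block size
    y <- matrix(rnorm(23 * 4), 23, 4)
    expect_equal(cosineDistanceMatrix(y, block = 5L),
                 cosineDistanceMatrix(y, block = 1000L), tolerance = 1e-12)
    d <- cosineDistanceMatrix(y)
    expect_lt(max(abs(d - t(d))), 1e-12)
    # duplicated row -> zero off-diagonal entry
    z <- rbind(y, y[1, ])
    expect_equal(cosineDistanceMatrix(z)[1, 24], 0, tolerance = 1e-12)
    # zero row is a named domain error
    bad <- y; bad[3, ] <- 0; rownames(bad) <- paste0("cell", 1:23)
    expect_error(cosineDistanceMatrix(bad), "cell3")
})

test_that("per-cell silhouette agrees with the brute-force oracle", {
    for (seed in 1:12) {
        inst <- randomInstance(seed, nMax = 60)
        rep <- silhouetteSamples(inst$x, inst$labels)
        ora <- oracleSilhouette(inst$x, inst$labels)
        got <- cellScores(rep)
        expect_equal(got$s, ora$s, tolerance = 1e-10)
        expect_equal(got$a, ora$a, tolerance = 1e-10)
        expect_equal(got$b, ora$b, tolerance = 1e-10)
        expect_true(all(got$s >= -1 - 1e-12 & got$s <= 1 + 1e-12))
    }
})

test_that("silhouette agrees with the cluster package under cosine", {
    skip_if_not_installed("cluster")
    for (seed in 1:8) {
        inst <- randomInstance(seed + 100, nMax = 80)
        rep <- silhouetteSamples(inst$x, inst$labels)
        d <- oracleCosMatrix(inst$x)
        sil <- cluster::silhouette(as.integer(inst$labels), dmatrix = d)
        expect_equal(cellScores(rep)$s, unname(sil[, "sil_width"]),
                     tolerance = 1e-8)
    }
})

test_that("two tight, far-separated blobs score near 1", {
    blobs <- makeBlobs(c(40, 40),
                       centers = rbind(c(10, 0), c(0, 10)),
                       sd = 0.5, seed = 3)
    rep <- silhouetteSamples(blobs$x, blobs$labels)
    expect_true(all(cellScores(rep)$s > 0.9))
})

test_that("formula edge cases: a == b gives 0; singletons score 0", {
    # orthogonal basis vectors: every pairwise cosine distance is 1, so
    # a(i) = b(i) for every cell and the score is exactly 0
    x <- diag(4)
    rownames(x) <- paste0("c", 1:4)
    rep <- silhouetteSamples(x, factor(c(1, 1, 2, 2)))
    expect_equal(cellScores(rep)$s, rep(0, 4), tolerance = 1e-12)

    inst <- randomInstance(5)
    lab <- as.character(inst$labels)
    lab[1] <- "lonely"
    rep2 <- silhouetteSamples(inst$x, lab)
    pc <- cellScores(rep2)
    expect_identical(pc$s[pc$cluster == "lonely"], 0)
    expect_true(is.na(pc$a[pc$cluster == "lonely"]))
    ora <- oracleSilhouette(inst$x, lab)
    expect_equal(pc$s, ora$s, tolerance = 1e-10)
})

test_that("a single cluster is a domain error", {
    inst <- randomInstance(9)
    expect_error(silhouetteSamples(inst$x, rep("A", nrow(inst$x))),
                 "single cluster")
})

test_that("permuting cell order permutes the scores identically", {
    inst <- randomInstance(31)
    rep <- silhouetteSamples(inst$x, inst$labels)
    perm <- sample(nrow(inst$x))
    rep2 <- silhouetteSamples(inst$x[perm, ], inst$labels[perm])
    expect_equal(cellScores(rep2)$s, cellScores(rep)$s[perm],
                 tolerance = 1e-12)
})

test_that("moving two blobs apart raises both cluster coefficients", {
    prev <- c(-Inf, -Inf)
    for (sep in c(2, 4, 8)) {
        blobs <- makeBlobs(c(30, 30),
                           centers = rbind(c(sep, 0), c(0, sep)),
                           sd = 1, seed = 17)
        cs <- clusterScores(silhouetteSamples(blobs$x, blobs$labels))
        expect_true(all(cs$coef > prev))
        prev <- cs$coef
    }
})

test_that("cluster coefficient and median summarise the per-cell scores", {
    inst <- randomInstance(23)
    rep <- silhouetteSamples(inst$x, inst$labels)
    pc <- cellScores(rep); cs <- clusterScores(rep)
    for (i in seq_len(nrow(cs))) {
        sel <- pc$s[pc$cluster == cs$cluster[i]]
        expect_equal(cs$coef[i], mean(sel))
        expect_equal(cs$median[i], median(sel))
        expect_identical(cs$n[i], length(sel))
    }
    # the arithmetic anchors
    toy <- methods::new("SilhouetteReport",
        perCell = S4Vectors::DataFrame(
            cell_id = paste0("c", 1:3), cluster = "A",
            a = rep(0.1, 3), b = rep(0.5, 3), s = c(0.2, 0.4, 0.9)),
        perCluster = S4Vectors::DataFrame(cluster = character(),
            n = integer(), coef = numeric(), median = numeric()),
        subsampled = FALSE)
    cs2 <- clusterScores(clusterCoefficients(toy))
    expect_equal(cs2$coef, 0.5)
    expect_equal(cs2$median, 0.4)
})

test_that("subsampling caps the scored cells but keeps every cluster", {
    blobs <- makeBlobs(c(300, 300, 60),
                       centers = rbind(c(8, 0), c(0, 8), c(6, 6)),
                       sd = 1, seed = 8)
    rep <- silhouetteSamples(blobs$x, blobs$labels, cap = 200,
                             minPerCluster = 50, seed = 4)
    expect_true(rep@subsampled)
    pc <- cellScores(rep)
    expect_lt(nrow(pc), 660)
    expect_setequal(unique(pc$cluster), levels(blobs$labels))
    expect_gte(min(table(pc$cluster)), 50)
})

test_that("silhouette reports write as TSV", {
    inst <- randomInstance(2)
    rep <- silhouetteSamples(inst$x, inst$labels)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeSilhouetteReport(rep, f1, f2)
    cells <- read.delim(f1)
    expect_identical(colnames(cells), c("cell_id", "cluster", "a", "b", "s"))
    expect_identical(nrow(cells), nrow(inst$x))
    summ <- read.delim(f2)
    expect_identical(colnames(summ), c("cluster", "n", "coef", "median"))
})
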