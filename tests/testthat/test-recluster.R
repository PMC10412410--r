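test_that("flagging follows the median threshold and force lists", {
    summ <- data.frame(cluster = c("A", "B"), n = c(100, 50),
                       coef = c(0.6, 0.1), median = c(0.6, 0.1))
    expect_identical(flagCandidates(summ, 0.25), "B")
    expect_identical(flagCandidates(summ, 0.25, forceInclude = "A"),
                     c("B", "A"))
    expect_identical(flagCandidates(summ, 0.25, forceExclude = "B"),
                     character(0))
    summ$median <- c(0.6, 0.5)
    expect_identical(flagCandidates(summ, 0.25), character(0))
    expect_error(flagCandidates(summ, 0.25, forceInclude = "Z"),
                 "unknown cluster")
    # ascending-median ordering
    summ3 <- data.frame(cluster = c("A", "B", "C"),
                        median = c(0.2, 0.05, 0.15))
    expect_identical(flagCandidates(summ3, 0.25), c("B", "C", "A"))
})

test_that("the parameter grid validates its inputs", {
    g <- paramGrid()
    expect_identical(nrow(g), 20L)
    expect_identical(colnames(g), c("k", "r", "n_pcs", "n_hvgs"))
    expect_error(paramGrid(k = integer()), "parameter error")
    expect_error(paramGrid(r = -1), "parameter error")
})

# A raw-count fixture whose single "broad cluster" secretly contains two
# subpopulations, next to one well-separated homogeneous cluster.
makeHiddenSplit <- function(seed = 1, nHidden = 60, nOther = 120,
                            effect = 6) {
    set.seed(seed)
    nGenes <- 300
    base <- rlnorm(nGenes, 0, 1)
    truth <- rep(c("P.a", "P.b", "O"), c(nHidden / 2, nHidden / 2, nOther))
    lfc <- matrix(0, nGenes, 3,
                  dimnames = list(NULL, c("P.a", "P.b", "O")))
    lfc[1:40, "O"] <- log2(effect)          # O far from P
    lfc[41:60, "P.a"] <- log2(effect)       # the hidden split
    lfc[61:80, "P.b"] <- log2(effect)
    mu <- base * 2^lfc[, truth]
    counts <- matrix(rnbinom(nGenes * length(truth), mu = mu, size = 2),
                     nGenes, length(truth),
                     dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                     sprintf("c%03d", seq_along(truth))))
    broad <- setNames(factor(ifelse(truth == "O", "O", "P")),
                      colnames(counts))
    list(counts = counts, truth = truth, broad = broad)
}

test_that("reclustering splits a cluster with genuine substructure and the
           reported best is the exact grid argmax", {
    fix <- makeHiddenSplit(seed = 42)
    res <- reclusterOne(fix$counts, fix$broad, "P",
                        grid = paramGrid(k = c(10L, 20L),
                                         r = c(0.6, 1.0), nHVGs = 100L),
                        seed = 7)
    g <- gridReport(res)
    expect_false(is.na(res@best))
    adm <- which(g$admissible)
    expect_gte(g$coef[res@best], max(g$coef[adm]) - 1e-12)
    sub <- subLabels(res)
    expect_setequal(names(sub), names(fix$broad)[fix$broad == "P"])
    truthP <- fix$truth[match(names(sub), colnames(fix$counts))]
    expect_equal(adjustedRandIndex(truthP, sub), 1)
})

test_that("a homogeneous cluster yields no substructure or an incoherent
           best split", {
    set.seed(9)
    nGenes <- 200
    counts <- matrix(rnbinom(nGenes * 150, mu = rlnorm(nGenes), size = 2),
                     nGenes, 150,
                     dimnames = list(sprintf("g%03d", 1:nGenes),
                                     sprintf("c%03d", 1:150)))
    # a second, distinct cluster so labels are well-formed
    other <- matrix(rnbinom(nGenes * 60, mu = rlnorm(nGenes) *
                            2^(sample(0:1, nGenes, TRUE) * 2), size = 2),
                    nGenes, 60,
                    dimnames = list(rownames(counts),
                                    sprintf("d%03d", 1:60)))
    all_counts <- cbind(counts, other)
    labels <- setNames(factor(rep(c("H", "X"), c(150, 60))),
                       colnames(all_counts))
    res <- reclusterOne(all_counts, labels, "H", seed = 3)
    if (!is.na(res@best)) {
        expect_lt(gridReport(res)$coef[res@best], 0.1)
    } else {
        expect_identical(length(subLabels(res)), 0L)
    }
})

test_that("reclustering preconditions are enforced", {
    fix <- makeHiddenSplit(seed = 1)
    expect_error(reclusterOne(fix$counts, fix$broad, "nope", seed = 1),
                 "unknown candidate")
    expect_error(reclusterOne(fix$counts, fix$broad, "P", minSubset = 500,
                              seed = 1), "minimum")
    expect_error(reclusterOne(fix$counts, fix$broad, "P",
                              grid = paramGrid()[0, ], seed = 1), "empty")
})

test_that("a one-point grid returns that point when admissible", {
    fix <- makeHiddenSplit(seed = 5)
    res <- reclusterOne(fix$counts, fix$broad, "P",
                        grid = paramGrid(k = 10L, r = 1.0, nHVGs = 100L),
                        seed = 2)
    if (!is.na(res@best)) expect_identical(res@best, 1L)
    expect_identical(nrow(gridReport(res)), 1L)
})

test_that("label integration is hierarchical, conservative and total", {
    global <- setNames(factor(rep(c("A", "B", "C"), c(5, 6, 4))),
                       paste0("c", 1:15))
    expect_identical(integrateLabels(global, list()),
                     factor(setNames(as.character(global), names(global))))

    sub <- setNames(factor(rep(c("0", "1"), c(3, 3))),
                    names(global)[global == "B"])
    res <- methods::new("ReclusterResult", candidate = "B",
                        cells = names(sub),
                        grid = data.frame(k = 10L, r = 0.5, n_pcs = 5L,
                                          n_hvgs = 50L, coef = 0.5,
                                          n_subclusters = 2L,
                                          admissible = TRUE),
                        best = 1L, subLabels = sub)
    out <- integrateLabels(global, res)
    expect_setequal(levels(out), c("A", "B.0", "B.1", "C"))
    expect_identical(length(out), length(global))
    # non-candidate cells are untouched, bit for bit
    keep <- global %in% c("A", "C")
    expect_identical(as.character(out)[keep], as.character(global)[keep])

    # overlapping candidates are rejected
    expect_error(integrateLabels(global, list(res, res)), "overlapping")

    # a no-substructure result changes nothing
    none <- methods::new("ReclusterResult", candidate = "C",
                         cells = names(global)[global == "C"],
                         grid = res@grid[0, ], best = NA_integer_,
                         subLabels = factor(character()))
    out2 <- integrateLabels(global, list(res, none))
    expect_identical(sum(out2 == "C"), 4L)
})

test_that("ReclusterResult validity rejects a non-argmax best", {
    g <- data.frame(k = c(10L, 20L), r = c(0.5, 0.5), n_pcs = 5L,
                    n_hvgs = 50L, coef = c(0.2, 0.6),
                    n_subclusters = 2L, admissible = TRUE)
    expect_error(methods::new("ReclusterResult", candidate = "A",
                              cells = c("c1", "c2"), grid = g, best = 1L,
                              subLabels = setNames(factor(c("0", "1")),
                                                   c("c1", "c2"))),
                 "maximum")
})
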