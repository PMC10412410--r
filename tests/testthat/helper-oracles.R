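# Independent oracles and fixture builders, written against the formulas
# directly; they deliberately share no code with the package internals.

# cosine distance, direct formula
.oracleCos <- function(a, b) 1 - sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# full cosine distance matrix by elementwise loops
oracleCosMatrix <- function(x) {
    n <- nrow(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (i != j) d[i, j] <- .oracleCos(x[i, ], x[j, ])
    d
}

# brute-force per-cell silhouette: mean intra distance with divisor
# |C|-1, minimum mean distance to each other cluster, (b-a)/max(a,b);
# singleton cells score 0
oracleSilhouette <- function(x, labels) {
    labels <- as.character(labels)
    n <- nrow(x)
    s <- numeric(n); av <- numeric(n); bv <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        if (length(own) == 1L) {
            av[i] <- NA_real_; s[i] <- 0
            others <- unique(labels[labels != labels[i]])
            bv[i] <- min(vapply(others, function(cl) {
                mean(vapply(which(labels == cl), function(j)
                    .oracleCos(x[i, ], x[j, ]), numeric(1)))
            }, numeric(1)))
            next
        }
        av[i] <- mean(vapply(setdiff(own, i), function(j)
            .oracleCos(x[i, ], x[j, ]), numeric(1)))
        others <- unique(labels[labels != labels[i]])
        bv[i] <- min(vapply(others, function(cl) {
            mean(vapply(which(labels == cl), function(j)
                .oracleCos(x[i, ], x[j, ]), numeric(1)))
        }, numeric(1)))
        s[i] <- (bv[i] - av[i]) / max(av[i], bv[i])
    }
    list(a = av, b = bv, s = s)
}

# Gaussian blob embedding with labelled ground truth; centers is a
# K x d matrix
makeBlobs <- function(sizes, centers, sd = 1, seed = 1) {
    set.seed(seed)
    k <- nrow(centers)
    x <- do.call(rbind, lapply(seq_len(k), function(i) {
        matrix(rnorm(sizes[i] * ncol(centers), sd = sd),
               ncol = ncol(centers)) +
            matrix(centers[i, ], sizes[i], ncol(centers), byrow = TRUE)
    }))
    rownames(x) <- paste0("cell", seq_len(nrow(x)))
    list(x = x, labels = factor(rep(seq_len(k), sizes)))
}

# random silhouette test instance: n cells, K clusters (each with at
# least minPer cells), d dims, no zero rows
randomInstance <- function(seed, nMax = 100, kMax = 6, dMax = 10,
                           minPer = 2) {
    set.seed(seed)
    k <- sample(2:kMax, 1)
    n <- sample((k * minPer):nMax, 1)
    d <- sample(2:dMax, 1)
    repeat {
        labels <- factor(sample(seq_len(k), n, replace = TRUE))
        if (nlevels(droplevels(labels)) == k &&
            min(table(labels)) >= minPer) break
    }
    x <- matrix(rnorm(n * d), n, d) +
         matrix(rnorm(k * d, sd = 2)[as.integer(labels)], n, d)
    rownames(x) <- paste0("c", seq_len(n))
    list(x = x, labels = labels)
}

# small raw-count fixture with two planted groups differing on a known,
# well-expressed gene set (multiplicative effect on the second group)
makeTwoGroupCounts <- function(nCells = 120, nGenes = 100, nDe = 10,
                               effect = 4, seed = 1) {
    set.seed(seed)
    base <- rlnorm(nGenes, 1, 0.5)
    # plant effects on solidly expressed (but not extreme) genes
    de <- which(base >= quantile(base, 0.5) & base <= quantile(base, 0.8))[seq_len(nDe)]
    grp <- rep(c("g1", "g2"), each = nCells / 2)
    mu <- outer(base, rep(1, nCells))
    mu[de, grp == "g2"] <- mu[de, grp == "g2"] * effect
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 4),
                     nGenes, nCells,
                     dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                     sprintf("c%03d", seq_len(nCells))))
    list(counts = counts, group = factor(grp),
         de_genes = rownames(counts)[de])
}
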