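# Count fixture for the two-step marker method: a target cluster with
# exclusive markers, a closely related sibling used as DE background, two
# large unrelated clusters, and "ubiquitous" genes high everywhere except
# the sibling — large fold-change against the background, yet useless as
# markers.
makeMarkerFixture <- function(seed = 1, effect = 8, nCells = 1000) {
    set.seed(seed)
    nGenes <- 300
    sizes <- round(nCells * c(T = 0.05, S = 0.05, O1 = 0.45, O2 = 0.45))
    truth <- rep(names(sizes), sizes)
    base <- rlnorm(nGenes, 0, 1)
    excl <- 1:10          # exclusive target markers
    ubiq <- 11:20         # high in T, O1, O2 but not in the sibling S
    base[excl] <- rlnorm(length(excl), 0, 0.3)   # moderate baseline
    base[ubiq] <- rlnorm(length(ubiq), 2, 0.2)   # abundant housekeepers
    sep  <- 21:60         # generic structure separating O1/O2/T+S
    fold <- matrix(1, nGenes, 4, dimnames = list(NULL, names(sizes)))
    fold[excl, "T"] <- effect
    fold[ubiq, c("T", "O1", "O2")] <- effect
    fold[sep[1:20], "O1"] <- 4
    fold[sep[21:40], "O2"] <- 4
    mu <- base * fold[, truth]
    counts <- matrix(rnbinom(nGenes * length(truth), mu = mu, size = 2),
                     nGenes, length(truth),
                     dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                     sprintf("c%04d", seq_along(truth))))
    list(norm = logNormalize(counts),
         labels = setNames(factor(truth), colnames(counts)),
         exclusive = rownames(counts)[excl],
         ubiquitous = rownames(counts)[ubiq])
}
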