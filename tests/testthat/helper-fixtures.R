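# Fixtures are built in code; no binary data on disk.

# dataset from an explicit matrix (genes x samples) and labels
makeDataset <- function(values, labels, geneIds = NULL, sampleIds = NULL) {
    values <- as.matrix(values)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(values)))
    if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(ncol(values)))
    TwoClassExpression(values, labels, geneIds = geneIds,
                       sampleIds = sampleIds)
}

# seeded Gaussian noise dataset with no class signal
noiseDataset <- function(nGenes, n1, n2, seed)
    simulateTwoClassData(n1 = n1, n2 = n2, nGenes = nGenes,
                         nInformative = 0, seed = seed)$dataset

# random small instance for cut-point oracle tests: expression values with
# frequent ties, random two-class labels with both classes present
randomCutInstance <- function(n) {
    expr <- sample(seq_len(max(2L, n %/% 2L)), n, replace = TRUE) +
        sample(c(0, 0.5), n, replace = TRUE)
    repeat {
        lab <- factor(sample(c("a", "b"), n, replace = TRUE),
                      levels = c("a", "b"))
        if (nlevels(droplevels(lab)) == 2L) break
    }
    list(expr = as.numeric(expr), labels = lab)
}

# independent entropy oracle: tabulates the partition and sums -p log2 p
# directly, sharing no code with partitionEntropy()
oracleEntropy <- function(expr, labels, t) {
    side <- factor(expr <= t, levels = c(TRUE, FALSE))
    tab <- table(side, labels)
    n <- length(expr)
    total <- 0
    for (s in 1:2) {
        m <- sum(tab[s, ])
        if (m == 0) next
        h <- 0
        for (cl in 1:2) {
            p <- tab[s, cl] / m
            if (p > 0) h <- h - p * log2(p)
        }
        total <- total + (m / n) * h
    }
    total
}

# exhaustive cut-point oracle over the documented candidate set:
# stable sort, class-boundary midpoints, trivial (empty-side) cuts dropped
oracleOptimalCut <- function(expr, labels) {
    n <- length(expr)
    ord <- order(expr)
    e <- expr[ord]; l <- labels[ord]
    P <- c()
    for (k in seq_len(n - 1)) {
        if (l[k] != l[k + 1]) P <- c(P, (e[k] + e[k + 1]) / 2)
    }
    P <- sort(unique(P[P < max(expr)]))
    if (length(P) == 0)
        return(list(cutPoint = mean(expr), fallback = TRUE,
                    entropy = oracleEntropy(expr, labels, mean(expr))))
    ents <- sapply(P, function(t) oracleEntropy(expr, labels, t))
    best <- which(ents == min(ents))[1]     # smallest t on ties
    list(cutPoint = P[best], fallback = FALSE, entropy = ents[best])
}
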