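#' Per-gene univariate scores and top-gene selection
#'
#' Row-wise two-sample statistics over all genes, computed with vectorised
#' arithmetic so that they can be re-run inside every cross-validation fold.
#' Statistics are oriented class 1 minus class 2 (t) or as the Mann-Whitney
#' U of class 1 (wmw). Two-sided p-values throughout.
#'
#' Degenerate genes: when the pooled sample is constant the gene carries no
#' information, gets p = 1 and is flagged \code{degenerate}. When both
#' within-class variances are zero but the class means differ (a constant
#' offset, i.e. perfect separation) the t-test p-value is 0 with an infinite
#' statistic carrying the sign of the mean difference; such genes are
#' informative and selectable.
#'
#' @param dataset a \linkS4class{TwoClassExpression}; every class must have
#'   >= 2 samples.
#' @param method \code{"t"} (default, pooled-variance two-sample t) or
#'   \code{"wmw"} (Wilcoxon-Mann-Whitney rank-sum).
#' @param varEqual pooled-variance t when TRUE (default); Welch otherwise.
#' @param exactLimit WMW only: exact null distribution is used when the
#'   pooled sample size is at most this and there are no ties; otherwise the
#'   normal approximation with tie and continuity correction.
#'
#' @return \code{scoreAllGenes}: a \link[S4Vectors]{DataFrame} with columns
#'   \code{geneId}, \code{orderNumber}, \code{statistic}, \code{pValue},
#'   \code{degenerate}, \code{method}, ordered by ascending p-value with
#'   ties broken by ascending order number (the deterministic selection
#'   order). \code{selectTopGene}: the first row of that ordering.
#'   \code{significantGenes}: the rows with \code{pValue < alpha}, order
#'   preserved.
#'
#' @examples
#' sim <- simulateTwoClassData(n1 = 10, n2 = 10, nGenes = 50,
#'                             nInformative = 1, effectSizes = 4, seed = 1)
#' top <- selectTopGene(sim$dataset)
#' top$geneId == sim$truth$informativeGenes
#' @name geneScores
NULL

# vectorised row-wise two-sample t: X is genes x samples
rowTStats <- function(X, idx1, idx2, varEqual = TRUE) {
    n1 <- length(idx1); n2 <- length(idx2)
    x1 <- X[, idx1, drop = FALSE]; x2 <- X[, idx2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    if (varEqual) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep.int(n1 + n2 - 2, length(se))
    } else {
        w1 <- v1 / n1; w2 <- v2 / n2
        se <- sqrt(w1 + w2)
        df <- (w1 + w2)^2 / (w1^2 / (n1 - 1) + w2^2 / (n2 - 1))
    }
    d <- m1 - m2
    stat <- d / se
    p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    zero <- se == 0
    degen <- zero & d == 0            # constant pooled sample: uninformative
    sep <- zero & d != 0              # constant offset: perfect separation
    stat[degen] <- 0; p[degen] <- 1
    stat[sep] <- sign(d[sep]) * Inf; p[sep] <- 0
    list(statistic = unname(stat), pValue = unname(p),
         degenerate = unname(degen))
}

# one gene's WMW score; r-free scalar version used row-wise
wmwOne <- function(x1, x2, exactLimit = 20L) {
    n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
    r <- rank(c(x1, x2))              # mid-ranks for ties
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- length(unique(r)) < N
    if (!ties && N <= exactLimit) {
        pl <- stats::pwilcox(U, n1, n2)
        pg <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        p <- min(1, 2 * min(pl, pg))
        return(c(U, p, 0))
    }
    nt <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0)                  # all values identical
        return(c(U, 1, 1))
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    c(U, p, 0)
}

rowWmwStats <- function(X, idx1, idx2, exactLimit = 20L) {
    res <- t(vapply(seq_len(nrow(X)), function(i)
        wmwOne(X[i, idx1], X[i, idx2], exactLimit), numeric(3)))
    list(statistic = res[, 1], pValue = res[, 2],
         degenerate = res[, 3] > 0)
}

#' @rdname geneScores
#' @export
scoreAllGenes <- function(dataset, method = c("t", "wmw"), varEqual = TRUE,
                          exactLimit = 20L) {
    method <- match.arg(method)
    checkTrainable(dataset)
    lab <- classLabels(dataset)
    lv <- levels(lab)
    X <- exprValues(dataset)
    idx1 <- which(lab == lv[1]); idx2 <- which(lab == lv[2])
    s <- if (method == "t") rowTStats(X, idx1, idx2, varEqual)
         else rowWmwStats(X, idx1, idx2, exactLimit)
    res <- S4Vectors::DataFrame(
        geneId = geneIds(dataset),
        orderNumber = orderNumbers(dataset),
        statistic = s$statistic,
        pValue = s$pValue,
        degenerate = s$degenerate,
        method = method)
    res[order(res$pValue, res$orderNumber), , drop = FALSE]
}

#' @rdname geneScores
#' @export
selectTopGene <- function(dataset, method = c("t", "wmw"), varEqual = TRUE,
                          exactLimit = 20L) {
    scores <- scoreAllGenes(dataset, method, varEqual, exactLimit)
    if (all(scores$degenerate))
        stop("no informative gene: all genes are degenerate (constant)")
    scores[1L, , drop = FALSE]
}

#' @rdname geneScores
#' @param alpha significance level in (0, 1); genes with p-value strictly
#'   below it are kept.
#' @export
significantGenes <- function(dataset, alpha = 0.001,
                             method = c("t", "wmw"), varEqual = TRUE,
                             exactLimit = 20L) {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
    scores <- scoreAllGenes(dataset, method, varEqual, exactLimit)
    scores[scores$pValue < alpha & !scores$degenerate, , drop = FALSE]
}

#' Two-sample scores for a single gene
#'
#' Convenience scalar forms of the per-gene statistics: \code{tScore} is the
#' two-sided two-sample t-test (pooled-variance by default, Welch via
#' \code{varEqual = FALSE}), \code{wmwScore} the two-sided
#' Wilcoxon-Mann-Whitney rank-sum test (exact when the pooled size is at
#' most \code{exactLimit} with no ties, else normal approximation with tie
#' and continuity correction; the statistic is the Mann-Whitney U of the
#' first group). Degenerate handling as in [scoreAllGenes()].
#'
#' @param x1,x2 numeric vectors, one per class, each of length >= 2
#' @inheritParams scoreAllGenes
#' @return list with \code{statistic}, \code{pValue}, \code{degenerate}
#' @examples
#' tScore(c(1.1, 2.0, 2.9), c(4.8, 6.1, 7.0))
#' wmwScore(1:3, 4:6)$pValue  # exact: 2 / choose(6, 3)
#' @export
tScore <- function(x1, x2, varEqual = TRUE) {
    stopifnot(length(x1) >= 2L, length(x2) >= 2L)
    s <- rowTStats(matrix(c(x1, x2), nrow = 1), seq_along(x1),
                   length(x1) + seq_along(x2), varEqual)
    lapply(s, `[[`, 1L)
}

#' @rdname tScore
#' @export
wmwScore <- function(x1, x2, exactLimit = 20L) {
    stopifnot(length(x1) >= 2L, length(x2) >= 2L)
    r <- wmwOne(x1, x2, exactLimit)
    list(statistic = r[1], pValue = r[2], degenerate = r[3] > 0)
}
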