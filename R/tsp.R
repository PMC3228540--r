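#' Top-scoring pair classifier
#'
#' The classical single-pair relative-expression classifier. For every
#' gene pair (i, j) it estimates, within each class, the frequency with
#' which gene i is expressed below gene j in the same sample, and scores
#' the pair by the absolute between-class difference of those frequencies
#' \eqn{\Delta_{ij} = | \hat P(X_i < X_j \mid c_1) - \hat P(X_i < X_j \mid
#' c_2) |}. The maximal-\eqn{\Delta} pair is selected; ties are broken by
#' the secondary rank score (absolute between-class difference of the mean
#' within-sample rank difference of the two genes), then by the smallest
#' gene order numbers. No significance pre-filter is applied — the rule is
#' rank-based and self-contained, and is invariant to any strictly
#' increasing transform of the expression values.
#'
#' Prediction: a sample with \eqn{X_i < X_j} is assigned the class whose
#' training frequency of that ordering is higher; otherwise (including
#' exact ties \eqn{X_i = X_j}) the other class.
#'
#' @inheritParams loocv
#' @return a \linkS4class{TSPModel}
#' @examples
#' sim <- simulateTwoClassData(n1 = 8, n2 = 8, nGenes = 15,
#'                             nInformative = 1, effectSizes = 6, seed = 2)
#' m <- trainTSP(sim$dataset)
#' m@genePanel
#' @export
trainTSP <- function(dataset) {
    checkTrainable(dataset)
    X <- exprValues(dataset)
    p <- nrow(X)
    if (p < 2L) stop("TSP needs at least 2 genes")
    lab <- classLabels(dataset)
    lv <- levels(lab)
    i1 <- lab == lv[1]; i2 <- lab == lv[2]
    R <- apply(X, 2, rank)                     # within-sample gene ranks
    best <- NULL
    for (i in seq_len(p - 1L)) {
        rest <- (i + 1L):p
        less <- sweep(X[rest, , drop = FALSE], 2, X[i, ], FUN = ">")
        # less[j, s] is TRUE when X_i < X_j in sample s
        p1 <- rowMeans(less[, i1, drop = FALSE])
        p2 <- rowMeans(less[, i2, drop = FALSE])
        delta <- abs(p1 - p2)
        rdiff <- sweep(R[rest, , drop = FALSE], 2, R[i, ])
        gamma <- abs(rowMeans(rdiff[, i1, drop = FALSE]) -
                     rowMeans(rdiff[, i2, drop = FALSE]))
        for (jj in seq_along(rest)) {
            cand <- list(i = i, j = rest[jj],
                         delta = unname(delta[jj]), gamma = unname(gamma[jj]),
                         p1 = unname(p1[jj]), p2 = unname(p2[jj]))
            if (is.null(best) ||
                cand$delta > best$delta ||
                (cand$delta == best$delta && cand$gamma > best$gamma))
                best <- cand
        }
    }
    if (best$delta == 0)
        stop("no discriminative pair: all pair scores are zero")
    ons <- orderNumbers(dataset)
    lessClass <- if (best$p1 >= best$p2) lv[1] else lv[2]
    geqClass <- setdiff(lv, lessClass)
    methods::new("TSPModel", kind = "tsp",
                 genePanel = geneIds(dataset)[c(best$i, best$j)],
                 panelOrder = ons[c(best$i, best$j)],
                 classLevels = lv, alpha = NA_real_, panelFallback = FALSE,
                 lessClass = lessClass, geqClass = geqClass,
                 delta = best$delta, rankScore = best$gamma,
                 p1 = best$p1, p2 = best$p2)
}

#' @rdname trainTSP
#' @param object a \linkS4class{TSPModel}
#' @param newdata a \linkS4class{TwoClassExpression} containing the pair
#' @param ... unused
#' @export
setMethod("predict", "TSPModel", function(object, newdata, ...) {
    idx <- panelRowIndex(object, newdata)
    X <- exprValues(newdata)[idx, , drop = FALSE]
    pred <- ifelse(X[1, ] < X[2, ], object@lessClass, object@geqClass)
    factor(pred, levels = object@classLevels)
})
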