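#' Standard comparator classifiers
#'
#' Baseline classifiers run against the single-gene models: diagonal linear
#' discriminant analysis (DLDA), k-nearest neighbours (k = 3), linear
#' soft-margin SVM, and random forest (100 trees, floor(sqrt(p)) candidate
#' genes per split). Each is trained on the gene panel passing the
#' univariate t-test filter at \code{alpha} computed from the training data
#' only; wrapped in [loocv()] the filter therefore re-runs inside every
#' fold. When the filter returns no gene, the single smallest-p gene is
#' used as a one-gene panel (\code{panelFallback} flag set).
#'
#' DLDA stores per-gene class means and pooled per-gene variances and
#' assigns the class minimising \eqn{\sum_g (x_g - \mu_{cg})^2 /
#' \sigma^2_g}; distance ties go to class 1. A zero pooled variance is
#' floored at \code{1e-8} times the gene's mean absolute expression (or
#' 1e-8 when that is also zero). k-NN uses Euclidean distance over the
#' panel; neighbour order breaks distance ties by smaller training-sample
#' index, and an (impossible at k = 3) vote tie falls to the nearest
#' neighbour's class. The SVM delegates to \code{e1071::svm} (linear
#' kernel, no internal rescaling); the forest to
#' \code{randomForest::randomForest} seeded explicitly — the only
#' stochastic comparator.
#'
#' @inheritParams loocv
#' @param alpha significance level of the univariate t-test gene filter
#' @param k number of neighbours (default 3)
#' @param cost SVM soft-margin cost (default 1)
#' @param nTrees number of trees (default 100)
#' @param mtry genes sampled per split; default floor(sqrt(panel size))
#' @param seed integer seed for the random forest
#' @return a fitted \linkS4class{ComparatorModel} subclass
#' @examples
#' sim <- simulateTwoClassData(n1 = 10, n2 = 10, nGenes = 60,
#'                             nInformative = 2, effectSizes = c(4, 4),
#'                             seed = 11)
#' m <- trainDLDA(sim$dataset)
#' mean(predict(m, sim$dataset) == classLabels(sim$dataset))
#' @name comparators
NULL

# alpha filter shared by all comparators; falls back to the top gene
filterPanel <- function(dataset, alpha, varEqual = TRUE) {
    sig <- significantGenes(dataset, alpha, method = "t",
                            varEqual = varEqual)
    fallback <- nrow(sig) == 0L
    if (fallback)
        sig <- selectTopGene(dataset, method = "t", varEqual = varEqual)
    idx <- match(sig$orderNumber, orderNumbers(dataset))
    list(idx = idx, geneId = sig$geneId,
         orderNumber = sig$orderNumber, fallback = fallback)
}

# panel rows of a prediction-time dataset, matched by order number + id
panelRowIndex <- function(model, newdata) {
    idx <- match(model@panelOrder, orderNumbers(newdata))
    if (anyNA(idx) ||
        !identical(geneIds(newdata)[idx], model@genePanel))
        stop("gene panel mismatch: prediction data lack the model's genes")
    idx
}

#' @rdname comparators
#' @export
trainDLDA <- function(dataset, alpha = 0.001) {
    checkTrainable(dataset)
    pan <- filterPanel(dataset, alpha)
    X <- exprValues(dataset)[pan$idx, , drop = FALSE]
    lab <- classLabels(dataset)
    lv <- levels(lab)
    i1 <- which(lab == lv[1]); i2 <- which(lab == lv[2])
    n1 <- length(i1); n2 <- length(i2)
    mu1 <- rowMeans(X[, i1, drop = FALSE])
    mu2 <- rowMeans(X[, i2, drop = FALSE])
    v1 <- rowSums((X[, i1, drop = FALSE] - mu1)^2)
    v2 <- rowSums((X[, i2, drop = FALSE] - mu2)^2)
    s2 <- (v1 + v2) / (n1 + n2 - 2)
    floorAt <- 1e-8 * pmax(rowMeans(abs(X)), 1)
    zero <- s2 <= 0
    if (any(zero)) {
        warning(sprintf("%d zero-variance gene(s) in DLDA panel; variance floored",
                        sum(zero)))
        s2[zero] <- floorAt[zero]
    }
    methods::new("DLDAModel", kind = "dlda", genePanel = pan$geneId,
                 panelOrder = pan$orderNumber, classLevels = lv,
                 alpha = alpha, panelFallback = pan$fallback,
                 mu1 = mu1, mu2 = mu2, pooledVar = s2)
}

#' @rdname comparators
#' @param object a fitted comparator model
#' @param newdata a \linkS4class{TwoClassExpression} sharing the model's
#'   gene panel
#' @param ... unused
#' @export
setMethod("predict", "DLDAModel", function(object, newdata, ...) {
    idx <- panelRowIndex(object, newdata)
    X <- exprValues(newdata)[idx, , drop = FALSE]
    d1 <- colSums((X - object@mu1)^2 / object@pooledVar)
    d2 <- colSums((X - object@mu2)^2 / object@pooledVar)
    pred <- ifelse(d1 <= d2, object@classLevels[1], object@classLevels[2])
    factor(pred, levels = object@classLevels)
})

#' @rdname comparators
#' @export
trainKNN <- function(dataset, alpha = 0.001, k = 3L) {
    checkTrainable(dataset)
    pan <- filterPanel(dataset, alpha)
    X <- exprValues(dataset)[pan$idx, , drop = FALSE]
    methods::new("KNNModel", kind = "knn3", genePanel = pan$geneId,
                 panelOrder = pan$orderNumber,
                 classLevels = levels(classLabels(dataset)),
                 alpha = alpha, panelFallback = pan$fallback,
                 trainValues = X, trainLabels = classLabels(dataset),
                 k = as.integer(k))
}

#' @rdname comparators
#' @export
setMethod("predict", "KNNModel", function(object, newdata, ...) {
    idx <- panelRowIndex(object, newdata)
    X <- exprValues(newdata)[idx, , drop = FALSE]
    k <- min(object@k, ncol(object@trainValues))
    lv <- object@classLevels
    pred <- vapply(seq_len(ncol(X)), function(j) {
        d <- sqrt(colSums((object@trainValues - X[, j])^2))
        nb <- order(d, seq_along(d))[seq_len(k)]   # ties: smaller index
        votes <- table(factor(object@trainLabels[nb], levels = lv))
        if (votes[1] == votes[2])
            as.character(object@trainLabels[nb[1]])  # tie: nearest
        else lv[which.max(votes)]
    }, character(1))
    factor(pred, levels = lv)
})

#' @rdname comparators
#' @export
trainSVMLinear <- function(dataset, alpha = 0.001, cost = 1) {
    checkTrainable(dataset)
    pan <- filterPanel(dataset, alpha)
    X <- t(exprValues(dataset)[pan$idx, , drop = FALSE])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    fit <- e1071::svm(x = X, y = classLabels(dataset), kernel = "linear",
                      cost = cost, scale = FALSE)
    methods::new("SVMModel", kind = "svm_linear", genePanel = pan$geneId,
                 panelOrder = pan$orderNumber,
                 classLevels = levels(classLabels(dataset)),
                 alpha = alpha, panelFallback = pan$fallback,
                 fit = fit, cost = cost)
}

#' @rdname comparators
#' @export
setMethod("predict", "SVMModel", function(object, newdata, ...) {
    idx <- panelRowIndex(object, newdata)
    X <- t(exprValues(newdata)[idx, , drop = FALSE])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    pred <- stats::predict(object@fit, X)
    factor(as.character(pred), levels = object@classLevels)
})

#' @rdname comparators
#' @export
trainRF <- function(dataset, alpha = 0.001, nTrees = 100L, mtry = NULL,
                    seed) {
    checkTrainable(dataset)
    stopifnot(is.numeric(seed), length(seed) == 1L)
    pan <- filterPanel(dataset, alpha)
    X <- t(exprValues(dataset)[pan$idx, , drop = FALSE])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
    mtry <- min(as.integer(mtry), ncol(X))
    fit <- withSeed(seed,
        randomForest::randomForest(x = X, y = classLabels(dataset),
                                   ntree = nTrees, mtry = mtry))
    methods::new("RFModel", kind = "rf", genePanel = pan$geneId,
                 panelOrder = pan$orderNumber,
                 classLevels = levels(classLabels(dataset)),
                 alpha = alpha, panelFallback = pan$fallback,
                 fit = fit, seed = as.integer(seed),
                 nTrees = as.integer(nTrees), mtry = mtry)
}

#' @rdname comparators
#' @export
setMethod("predict", "RFModel", function(object, newdata, ...) {
    idx <- panelRowIndex(object, newdata)
    X <- t(exprValues(newdata)[idx, , drop = FALSE])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    pred <- stats::predict(object@fit, X)
    factor(as.character(pred), levels = object@classLevels)
})
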