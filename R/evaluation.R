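#' Complete leave-one-out cross-validation
#'
#' Holds out each sample in turn and re-runs the \emph{entire} classifier
#' development on the remaining n - 1 samples — gene selection, cut-point
#' estimation, significance filtering, whatever the trainer does — so the
#' held-out sample never influences development (no leakage). The scheme is
#' deterministic; any randomness belongs to the trainer.
#'
#' @param dataset a \linkS4class{TwoClassExpression} with >= 3 samples per
#'   class (so every fold's training set keeps >= 2 per class)
#' @param trainer a function \code{function(dataset) -> model} whose result
#'   has \code{predict} and \code{genesUsed} methods; e.g.
#'   \code{sgcTrainer("t")} or [dldaTrainer()]
#' @return an \linkS4class{EvaluationResult} with overall and per-class
#'   held-out accuracy, mean genes per fold model, and per-gene occurrence
#'   percentages across folds (selection stability)
#' @examples
#' sim <- simulateTwoClassData(n1 = 8, n2 = 8, nGenes = 40,
#'                             nInformative = 1, effectSizes = 5, seed = 3)
#' res <- loocv(sim$dataset, sgcTrainer("t"))
#' res
#' @seealso [splitSample()], [evaluateSplit()], [geneStability()]
#' @export
loocv <- function(dataset, trainer) {
    stopifnot(is.function(trainer))
    n <- ncol(dataset)
    cc <- classCounts(dataset)
    if (any(cc < 3L))
        stop("a LOOCV fold would leave < 2 training samples in a class; ",
             "use split-sample evaluation instead")
    lab <- as.character(classLabels(dataset))
    folds <- vector("list", n)
    predicted <- character(n)
    for (i in seq_len(n)) {
        model <- trainer(dataset[, -i])
        p <- as.character(predict(model, dataset[, i]))
        predicted[i] <- p
        folds[[i]] <- list(heldOut = colnames(dataset)[i],
                           genes = genesUsed(model),
                           summary = modelSummary(model),
                           predicted = p, truth = lab[i])
    }
    aggregateEvaluation("loocv", folds, predicted, lab,
                        levels(classLabels(dataset)), NA_integer_)
}

# compact per-fold description kept in the evaluation report
modelSummary <- function(model) {
    if (methods::is(model, "SGClassifier"))
        list(geneId = model@geneId, cutPoint = model@cutPoint,
             direction = model@direction,
             pValue = model@trainingStats$pValue)
    else if (methods::is(model, "ComparatorModel"))
        list(kind = model@kind, panelSize = length(model@genePanel),
             panelFallback = model@panelFallback)
    else list(class = class(model)[1])
}

aggregateEvaluation <- function(scheme, folds, predicted, truth, lv, seed) {
    correct <- predicted == truth
    acc <- 100 * mean(correct)
    perClass <- vapply(lv, function(cl) {
        idx <- truth == cl
        if (!any(idx)) NA_real_ else 100 * mean(correct[idx])
    }, numeric(1))
    geneLists <- lapply(folds, `[[`, "genes")
    meanGenes <- mean(lengths(geneLists))
    occ <- table(unlist(lapply(geneLists, unique)))
    stab <- 100 * as.numeric(occ) / length(folds)
    names(stab) <- names(occ)
    stab <- stab[order(-stab, names(stab))]
    methods::new("EvaluationResult", scheme = scheme, folds = folds,
                 accuracyPct = acc, perClassAccuracyPct = perClass,
                 meanGenesPerModel = meanGenes, stability = stab,
                 seed = seed)
}

#' Gene selection stability across cross-validation folds
#'
#' The percentage of folds in which each gene was part of the fold's model
#' (for single-gene trainers: was \emph{the} selected gene, so the
#' percentages sum to 100). Descending order.
#'
#' @param object an \linkS4class{EvaluationResult}
#' @return named numeric vector of percentages
#' @export
setMethod("geneStability", "EvaluationResult",
          function(object) object@stability)

#' Stratified train/test splits
#'
#' Randomly separates the samples into one training and one test set,
#' stratified by class. Type 1 puts about half the samples in the training
#' set, type 2 about two thirds; the per-class training count is rounded
#' up. Deterministic given \code{seed}.
#'
#' @inheritParams loocv
#' @param type \code{"type1"} (train:test about 1:1) or \code{"type2"}
#'   (about 2:1)
#' @param seed integer random seed (required)
#' @return list with elements \code{train} and \code{test}, both
#'   \linkS4class{TwoClassExpression}
#' @export
splitSample <- function(dataset, type = c("type1", "type2"), seed) {
    type <- match.arg(type)
    stopifnot(is.numeric(seed), length(seed) == 1L)
    frac <- if (type == "type1") 1 / 2 else 2 / 3
    lab <- classLabels(dataset)
    trainIdx <- withSeed(seed, {
        unlist(lapply(levels(lab), function(cl) {
            idx <- which(lab == cl)
            sample(idx, ceiling(length(idx) * frac))
        }))
    })
    trainIdx <- sort(trainIdx)
    train <- dataset[, trainIdx]
    test <- dataset[, -trainIdx]
    for (part in list(train, test)) {
        tab <- table(classLabels(part))
        if (any(tab < 2L))
            stop(sprintf("class '%s' has < 2 samples in one part of the split",
                         names(tab)[which.min(tab)]))
    }
    list(train = train, test = test)
}

#' Split-sample evaluation
#'
#' Trains once on the training set and measures accuracy on the test set.
#' Both parts must share the same gene panel (identifiers and order
#' numbers).
#'
#' @param train,test \linkS4class{TwoClassExpression} parts from
#'   [splitSample()]
#' @param trainer as in [loocv()]
#' @param scheme label recorded in the result (\code{"split1"} or
#'   \code{"split2"})
#' @param seed seed recorded in the result (provenance only)
#' @return an \linkS4class{EvaluationResult} with a single fold
#' @export
evaluateSplit <- function(train, test, trainer,
                          scheme = "split1", seed = NA_integer_) {
    if (!identical(geneIds(train), geneIds(test)) ||
        !identical(orderNumbers(train), orderNumbers(test)))
        stop("gene panel mismatch between training and test sets")
    model <- trainer(train)
    p <- as.character(predict(model, test))
    truth <- as.character(classLabels(test))
    folds <- list(list(heldOut = colnames(test),
                       genes = genesUsed(model),
                       summary = modelSummary(model),
                       predicted = p, truth = truth))
    aggregateEvaluation(scheme, folds, p, truth,
                        levels(classLabels(train)), as.integer(seed))
}

#' Trainer factories
#'
#' Convenience closures conforming to the \code{trainer} contract of
#' [loocv()] and [evaluateSplit()]: \code{sgcTrainer} wraps [trainSGC()],
#' the comparator factories wrap [trainDLDA()], [trainKNN()],
#' [trainSVMLinear()], [trainRF()] and [trainTSP()] with their parameters
#' fixed, so the significance filter and all model development re-run on
#' each fold's training data.
#'
#' @inheritParams trainSGC
#' @param alpha significance level of the comparators' univariate gene
#'   filter
#' @param k number of neighbours
#' @param cost SVM soft-margin cost
#' @param nTrees number of random-forest trees
#' @param seed random-forest seed (the only stochastic comparator)
#' @return a function \code{function(dataset) -> model}
#' @export
sgcTrainer <- function(method = c("t", "wmw"), varEqual = TRUE,
                       exactLimit = 20L) {
    method <- match.arg(method)
    function(dataset) trainSGC(dataset, method, varEqual, exactLimit)
}

#' @rdname sgcTrainer
#' @export
dldaTrainer <- function(alpha = 0.001)
    function(dataset) trainDLDA(dataset, alpha)

#' @rdname sgcTrainer
#' @export
knnTrainer <- function(alpha = 0.001, k = 3L)
    function(dataset) trainKNN(dataset, alpha, k)

#' @rdname sgcTrainer
#' @export
svmTrainer <- function(alpha = 0.001, cost = 1)
    function(dataset) trainSVMLinear(dataset, alpha, cost)

#' @rdname sgcTrainer
#' @export
rfTrainer <- function(alpha = 0.001, nTrees = 100L, seed)
    function(dataset) trainRF(dataset, alpha, nTrees = nTrees, seed = seed)

#' @rdname sgcTrainer
#' @export
tspTrainer <- function() function(dataset) trainTSP(dataset)

#' Run several classifiers under one LOOCV
#'
#' Evaluates the two single-gene classifiers and any of the comparators
#' under complete leave-one-out cross-validation on the same dataset and
#' returns an accuracy / mean-gene-count summary table (one row per
#' method).
#'
#' @inheritParams loocv
#' @param methods subset of \code{c("sgc_t", "sgc_w", "dlda", "knn", "svm",
#'   "rf", "tsp")}
#' @param alpha comparator gene-filter significance level
#' @param seed seed for the random forest (required if \code{"rf"} is run)
#' @return \code{data.frame} with columns \code{method},
#'   \code{accuracyPct}, \code{meanGenes}, plus attribute
#'   \code{"results"}: the named list of \linkS4class{EvaluationResult}s
#' @export
compareClassifiers <- function(dataset,
                               methods = c("sgc_t", "sgc_w", "dlda", "knn",
                                           "svm", "rf", "tsp"),
                               alpha = 0.001, seed = NULL) {
    methods <- match.arg(methods, several.ok = TRUE)
    if ("rf" %in% methods && is.null(seed))
        stop("the random forest comparator needs an explicit seed")
    trainers <- list(
        sgc_t = sgcTrainer("t"), sgc_w = sgcTrainer("wmw"),
        dlda = dldaTrainer(alpha), knn = knnTrainer(alpha),
        svm = svmTrainer(alpha),
        rf = if ("rf" %in% methods) rfTrainer(alpha, seed = seed),
        tsp = tspTrainer())
    results <- lapply(methods, function(m) loocv(dataset, trainers[[m]]))
    names(results) <- methods
    out <- data.frame(
        method = methods,
        accuracyPct = vapply(results, methods::slot, numeric(1),
                             "accuracyPct"),
        meanGenes = vapply(results, methods::slot, numeric(1),
                           "meanGenesPerModel"),
        row.names = NULL)
    attr(out, "results") <- results
    out
}

#' Write an evaluation report as JSON
#'
#' Plain-JSON report with a schema version field: scheme, seed, overall
#' and per-class accuracy, mean genes per model, the stability table and
#' the per-fold records.
#'
#' @param result an \linkS4class{EvaluationResult}
#' @param path output file
#' @return the path, invisibly
#' @export
writeEvaluationReport <- function(result, path) {
    obj <- list(
        schema_version = "1.0",
        scheme = result@scheme,
        seed = if (is.na(result@seed)) NULL else result@seed,
        accuracy_pct = result@accuracyPct,
        per_class_accuracy_pct = as.list(result@perClassAccuracyPct),
        mean_genes_per_model = result@meanGenesPerModel,
        stability = lapply(seq_along(result@stability), function(i)
            list(gene_id = names(result@stability)[i],
                 occurrence_pct = unname(result@stability[i]))),
        folds = result@folds)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    invisible(path)
}
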