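#' Train a single-gene classifier
#'
#' Full development pipeline for one training set: pick the gene with the
#' smallest two-sided p-value under the chosen test (p-value ties resolve
#' to the smallest order number), place the entropy-minimising cut point on
#' that gene, and orient the decision rule so the majority of training
#' samples is classified correctly (an exact tie reverses the default
#' "left side is class 1" orientation, so training accuracy is always at
#' least 50%).
#'
#' @inheritParams scoreAllGenes
#' @return an \linkS4class{SGClassifier}
#' @examples
#' sim <- simulateTwoClassData(n1 = 10, n2 = 10, nGenes = 100,
#'                             nInformative = 1, effectSizes = 5, seed = 7)
#' model <- trainSGC(sim$dataset, method = "t")
#' model
#' table(predicted = predict(model, sim$dataset),
#'       truth = classLabels(sim$dataset))
#' @seealso [predict,SGClassifier-method], [writeModel()], [loocv()]
#' @export
trainSGC <- function(dataset, method = c("t", "wmw"), varEqual = TRUE,
                     exactLimit = 20L) {
    method <- match.arg(method)
    checkTrainable(dataset)
    top <- selectTopGene(dataset, method, varEqual, exactLimit)
    idx <- match(top$orderNumber, orderNumbers(dataset))
    expr <- exprValues(dataset)[idx, ]
    lab <- classLabels(dataset)
    lv <- levels(lab)
    cp <- optimalCutPoint(expr, lab)
    classes <- if (cp$direction == "leq_is_c1") lv else rev(lv)
    predTrain <- ifelse(expr <= cp$cutPoint, classes[1], classes[2])
    cc <- classCounts(dataset)
    model <- methods::new("SGClassifier",
        geneId = top$geneId, orderNumber = top$orderNumber,
        method = method, cutPoint = cp$cutPoint,
        direction = cp$direction, classes = classes, classLevels = lv,
        trainingStats = list(
            statistic = top$statistic, pValue = top$pValue,
            entropy = cp$entropy, candidateCount = cp$candidateCount,
            fallbackUsed = cp$fallbackUsed, n1 = cc[1], n2 = cc[2],
            trainingAccuracyPct = 100 * mean(predTrain == as.character(lab)),
            varEqual = varEqual, exactLimit = as.integer(exactLimit)))
    model
}

# locate the model's gene in a dataset: order number first, then identifier
geneRowIndex <- function(geneId, orderNumber, dataset) {
    idx <- which(orderNumbers(dataset) == orderNumber &
                 geneIds(dataset) == geneId)
    if (!length(idx))
        idx <- which(geneIds(dataset) == geneId)
    if (!length(idx))
        stop(sprintf("gene '%s' not present in the input dataset", geneId))
    idx[1L]
}

#' Predict classes with a single-gene classifier
#'
#' Applies the hard-threshold rule: expression at or below the cut point is
#' assigned the model's left-side class, expression above it the other
#' class. A value exactly equal to the cut point falls on the \code{<=}
#' side.
#'
#' @param object an \linkS4class{SGClassifier}
#' @param newdata a \linkS4class{TwoClassExpression} containing the model's
#'   gene, or a plain numeric vector of that gene's expression values
#' @param ... unused
#' @return factor of predicted class labels (levels in the training data's
#'   class order), named by sample when \code{newdata} carries sample ids
#' @export
setMethod("predict", "SGClassifier", function(object, newdata, ...) {
    if (methods::is(newdata, "TwoClassExpression")) {
        idx <- geneRowIndex(object@geneId, object@orderNumber, newdata)
        expr <- exprValues(newdata)[idx, ]
    } else if (is.numeric(newdata)) {
        expr <- newdata
    } else stop("newdata must be a TwoClassExpression or a numeric vector")
    pred <- ifelse(expr <= object@cutPoint, object@classes[1],
                   object@classes[2])
    factor(pred, levels = object@classLevels)
})

#' Serialize models to JSON
#'
#' Writes a fitted model to a plain-JSON file (schema version field
#' included) and reads it back losslessly; \code{readModel} of a written
#' single-gene classifier predicts identically to the original. Numeric
#' fields are written at full double precision. Supported for
#' \linkS4class{SGClassifier} and for the DLDA, k-NN and TSP comparators;
#' SVM and random-forest fits carry opaque third-party state and should be
#' persisted with \code{saveRDS}.
#'
#' @param model a supported model object
#' @param path file path to write to / read from
#' @return \code{writeModel}: the path, invisibly. \code{readModel}: the
#'   reconstructed model.
#' @export
writeModel <- function(model, path) {
    obj <- modelToList(model)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
    invisible(path)
}

# nonfinite doubles are not representable in JSON; tag them as strings
numJson <- function(x) {
    if (is.numeric(x) && length(x) == 1L && !is.finite(x))
        as.character(x) else x
}

modelToList <- function(model) {
    if (methods::is(model, "SGClassifier")) {
        st <- model@trainingStats
        return(list(schema_version = "1.0", model_type = "sgc",
             method = model@method, gene_id = model@geneId,
             order_number = model@orderNumber, cut_point = model@cutPoint,
             direction = model@direction,
             classes = as.list(model@classes),
             class_levels = as.list(model@classLevels),
             training_stats = lapply(st, numJson)))
    }
    if (methods::is(model, "DLDAModel"))
        return(list(schema_version = "1.0", model_type = "dlda",
             alpha = model@alpha, gene_panel = as.list(model@genePanel),
             panel_order = as.list(model@panelOrder),
             class_levels = as.list(model@classLevels),
             panel_fallback = model@panelFallback,
             mu1 = model@mu1, mu2 = model@mu2, pooled_var = model@pooledVar))
    if (methods::is(model, "KNNModel"))
        return(list(schema_version = "1.0", model_type = "knn",
             alpha = model@alpha, k = model@k,
             gene_panel = as.list(model@genePanel),
             panel_order = as.list(model@panelOrder),
             class_levels = as.list(model@classLevels),
             panel_fallback = model@panelFallback,
             train_values = apply(model@trainValues, 2, identity,
                                  simplify = FALSE),
             train_labels = as.character(model@trainLabels)))
    if (methods::is(model, "TSPModel"))
        return(list(schema_version = "1.0", model_type = "tsp",
             gene_panel = as.list(model@genePanel),
             panel_order = as.list(model@panelOrder),
             class_levels = as.list(model@classLevels),
             less_class = model@lessClass, geq_class = model@geqClass,
             delta = model@delta, rank_score = model@rankScore,
             p1 = model@p1, p2 = model@p2))
    stop("JSON serialization is not supported for this model class; use saveRDS")
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    switch(obj$model_type,
        sgc = {
            st <- obj$training_stats
            num <- function(v) if (is.character(v)) as.numeric(v) else v
            st <- lapply(st, num)
            st$fallbackUsed <- isTRUE(obj$training_stats$fallbackUsed)
            st$n1 <- as.integer(st$n1); st$n2 <- as.integer(st$n2)
            st$exactLimit <- as.integer(st$exactLimit)
            st$varEqual <- isTRUE(obj$training_stats$varEqual)
            st$candidateCount <- as.integer(st$candidateCount)
            methods::new("SGClassifier", geneId = obj$gene_id,
                orderNumber = as.integer(obj$order_number),
                method = obj$method, cutPoint = obj$cut_point,
                direction = obj$direction,
                classes = as.character(obj$classes),
                classLevels = as.character(obj$class_levels),
                trainingStats = st)
        },
        dlda = methods::new("DLDAModel", kind = "dlda",
            genePanel = as.character(obj$gene_panel),
            panelOrder = as.integer(obj$panel_order),
            classLevels = as.character(obj$class_levels),
            alpha = obj$alpha, panelFallback = isTRUE(obj$panel_fallback),
            mu1 = obj$mu1, mu2 = obj$mu2, pooledVar = obj$pooled_var),
        knn = methods::new("KNNModel", kind = "knn3",
            genePanel = as.character(obj$gene_panel),
            panelOrder = as.integer(obj$panel_order),
            classLevels = as.character(obj$class_levels),
            alpha = obj$alpha, panelFallback = isTRUE(obj$panel_fallback),
            trainValues = do.call(cbind, obj$train_values),
            trainLabels = factor(obj$train_labels,
                                 levels = as.character(obj$class_levels)),
            k = as.integer(obj$k)),
        tsp = methods::new("TSPModel", kind = "tsp",
            genePanel = as.character(obj$gene_panel),
            panelOrder = as.integer(obj$panel_order),
            classLevels = as.character(obj$class_levels),
            alpha = NA_real_, panelFallback = FALSE,
            lessClass = obj$less_class, geqClass = obj$geq_class,
            delta = obj$delta, rankScore = obj$rank_score,
            p1 = obj$p1, p2 = obj$p2),
        stop(sprintf("unknown model_type '%s' in %s", obj$model_type, path)))
}
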