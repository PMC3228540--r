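#' Two-class expression dataset
#'
#' An expression matrix (genes x samples) with a binary class label per
#' sample, stored as a \linkS4class{SummarizedExperiment}. Each gene carries
#' an \emph{order number}: its 0-based row position in the source file, used
#' as the deterministic tie-break when several genes reach the same p-value.
#' The first level of the label factor is class 1 (\code{c1}); readers set
#' the level order from the order of first appearance in the label file, so
#' the class named first is class 1.
#'
#' Duplicate gene identifiers are allowed (common on arrays); internal gene
#' identity is the pair (identifier, order number). Missing values are not
#' supported: readers and the constructor reject them.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}; the single assay
#'   \code{"exprs"} holds the expression values, \code{rowData()$orderNumber}
#'   the order numbers, \code{colData()$class} the label factor.
#'
#' @seealso [TwoClassExpression()], [readExpressionTSV()], [readGctCls()]
#' @export
setClass("TwoClassExpression", contains = "SummarizedExperiment")

setValidity("TwoClassExpression", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v))
            msg <- c(msg, "expression values must be numeric")
        else if (anyNA(v))
            msg <- c(msg, "missing expression values are not supported")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"class" %in% colnames(cd) || !is.factor(cd$class))
        msg <- c(msg, "colData()$class must be a factor of class labels")
    else {
        if (nlevels(cd$class) != 2L)
            msg <- c(msg, sprintf("exactly 2 class levels required, found %d",
                                  nlevels(cd$class)))
        if (anyNA(cd$class))
            msg <- c(msg, "class labels must not contain NA")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!"orderNumber" %in% colnames(rd))
        msg <- c(msg, "rowData()$orderNumber is required")
    else if (anyDuplicated(rd$orderNumber))
        msg <- c(msg, "gene order numbers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a TwoClassExpression dataset
#'
#' @param values numeric matrix, genes in rows, samples in columns. No NAs.
#' @param labels class label per sample (character or factor, length
#'   \code{ncol(values)}). For a character vector the two class levels are
#'   taken in order of first appearance; the first level is class 1.
#' @param geneIds gene identifiers; defaults to \code{rownames(values)}.
#'   Duplicates allowed.
#' @param sampleIds sample identifiers; defaults to \code{colnames(values)}.
#'   Must be unique.
#' @param orderNumbers 0-based gene order numbers; default
#'   \code{0:(nrow-1)}, i.e. row order as supplied.
#' @param metadata free-form provenance list (source files, expression
#'   scale, ...).
#'
#' @return a \linkS4class{TwoClassExpression}
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- TwoClassExpression(m, c("A", "A", "B", "B"))
#' classLabels(x)
#' @export
TwoClassExpression <- function(values, labels, geneIds = rownames(values),
                               sampleIds = colnames(values),
                               orderNumbers = NULL, metadata = list()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(geneIds))
        geneIds <- paste0("g", seq_len(nrow(values)))
    if (is.null(sampleIds))
        sampleIds <- paste0("s", seq_len(ncol(values)))
    if (anyDuplicated(sampleIds))
        stop("sample identifiers must be unique")
    if (length(labels) != ncol(values))
        stop(sprintf("%d labels for %d samples", length(labels), ncol(values)))
    if (!is.factor(labels))
        labels <- factor(labels, levels = unique(as.character(labels)))
    labels <- droplevels(labels)
    if (nlevels(labels) != 2L)
        stop(sprintf("exactly 2 classes required, found %d: %s",
                     nlevels(labels), paste(levels(labels), collapse = ", ")))
    if (is.null(orderNumbers))
        orderNumbers <- seq_len(nrow(values)) - 1L
    dimnames(values) <- list(geneIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        rowData = S4Vectors::DataFrame(orderNumber = as.integer(orderNumbers)),
        colData = S4Vectors::DataFrame(class = labels, row.names = sampleIds),
        metadata = metadata)
    methods::new("TwoClassExpression", se)
}

#' @describeIn TwoClassExpression-class summary printout
#' @param object a \code{TwoClassExpression}
#' @export
setMethod("show", "TwoClassExpression", function(object) {
    methods::callNextMethod()
    tab <- table(classLabels(object))
    cat(sprintf("classes(%d): %s\n", nlevels(classLabels(object)),
                paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                      collapse = ", ")))
})

#' Single-gene classifier
#'
#' A hard-threshold classifier on a single gene: a sample with expression
#' \code{<= cutPoint} on that gene is assigned \code{classes(model)[1]}, and
#' \code{classes(model)[2]} otherwise. The gene is the one with the smallest
#' two-sample t-test (or Wilcoxon-Mann-Whitney) p-value in the training set,
#' the cut point minimises the class information entropy of the induced
#' partition, and the direction is whichever orientation classifies more
#' training samples correctly (an exact tie reverses the default
#' orientation).
#'
#' @slot geneId selected gene identifier.
#' @slot orderNumber the gene's 0-based source-file row (tie-break identity).
#' @slot method \code{"t"} or \code{"wmw"} (gene selection test).
#' @slot cutPoint expression threshold, full precision.
#' @slot direction \code{"leq_is_c1"} or \code{"leq_is_c2"}, where c1 is the
#'   first class level of the training data.
#' @slot classes length-2 character: the class assigned on the
#'   \code{<= cutPoint} side, then the class on the \code{>} side.
#' @slot classLevels the training data's class levels in (c1, c2) order;
#'   predictions are returned as a factor with these levels.
#' @slot trainingStats list: selection statistic and p-value, partition
#'   entropy at the cut point, whether the empty-candidate mean fallback was
#'   used, per-class training sizes, training accuracy.
#'
#' @seealso [trainSGC()], [predict,SGClassifier-method], [writeModel()]
#' @export
setClass("SGClassifier",
    representation(geneId = "character", orderNumber = "integer",
                   method = "character", cutPoint = "numeric",
                   direction = "character", classes = "character",
                   classLevels = "character", trainingStats = "list"))

setValidity("SGClassifier", function(object) {
    msg <- character()
    if (length(object@classes) != 2L || anyDuplicated(object@classes))
        msg <- c(msg, "classes must be two distinct labels")
    if (!object@direction %in% c("leq_is_c1", "leq_is_c2"))
        msg <- c(msg, "direction must be leq_is_c1 or leq_is_c2")
    if (!object@method %in% c("t", "wmw"))
        msg <- c(msg, "method must be t or wmw")
    if (length(object@cutPoint) != 1L || !is.finite(object@cutPoint))
        msg <- c(msg, "cutPoint must be a single finite value")
    if (length(msg)) msg else TRUE
})

#' @describeIn SGClassifier-class summary printout
#' @param object an \code{SGClassifier}
#' @export
setMethod("show", "SGClassifier", function(object) {
    st <- object@trainingStats
    cat(sprintf("SGClassifier (SGC-%s)\n", object@method))
    cat(sprintf("  gene: %s (order number %d)\n",
                object@geneId, object@orderNumber))
    cat(sprintf("  rule: expr <= %.6g => %s ; expr > %.6g => %s\n",
                object@cutPoint, object@classes[1],
                object@cutPoint, object@classes[2]))
    cat(sprintf("  selection p-value: %.4g; partition entropy: %.4f%s\n",
                st$pValue, st$entropy,
                if (isTRUE(st$fallbackUsed)) " (mean fallback)" else ""))
    cat(sprintf("  training accuracy: %.1f%% (n = %d + %d)\n",
                st$trainingAccuracyPct, st$n1, st$n2))
})

#' Comparator classifier models
#'
#' Virtual parent of the standard comparison classifiers (DLDA, k-NN, linear
#' SVM, random forest, top-scoring pair). Except for TSP, each is trained on
#' the gene panel passing the univariate significance filter
#' (\code{p < alpha}, applied to the current training data only, so the
#' filter is re-run inside every cross-validation fold).
#'
#' @slot kind one of \code{"dlda"}, \code{"knn3"}, \code{"svm_linear"},
#'   \code{"rf"}, \code{"tsp"}.
#' @slot genePanel gene identifiers used by the model, in filter ranking
#'   order (for TSP, the selected pair).
#' @slot panelOrder the genes' 0-based order numbers (panel identity for
#'   prediction-time matching).
#' @slot classLevels training class levels, (c1, c2) order.
#' @slot alpha significance level of the filter (NA for TSP).
#' @slot panelFallback TRUE when the filter returned no gene and the single
#'   smallest-p gene was used instead.
#' @export
setClass("ComparatorModel",
    representation("VIRTUAL", kind = "character", genePanel = "character",
                   panelOrder = "integer", classLevels = "character",
                   alpha = "numeric", panelFallback = "logical"))

#' @rdname ComparatorModel-class
#' @export
setClass("DLDAModel", contains = "ComparatorModel",
    representation(mu1 = "numeric", mu2 = "numeric", pooledVar = "numeric"))

#' @rdname ComparatorModel-class
#' @export
setClass("KNNModel", contains = "ComparatorModel",
    representation(trainValues = "matrix", trainLabels = "factor",
                   k = "integer"))

#' @rdname ComparatorModel-class
#' @export
setClass("SVMModel", contains = "ComparatorModel",
    representation(fit = "ANY", cost = "numeric"))

#' @rdname ComparatorModel-class
#' @export
setClass("RFModel", contains = "ComparatorModel",
    representation(fit = "ANY", seed = "integer", nTrees = "integer",
                   mtry = "integer"))

#' @rdname ComparatorModel-class
#' @export
setClass("TSPModel", contains = "ComparatorModel",
    representation(lessClass = "character", geqClass = "character",
                   delta = "numeric", rankScore = "numeric",
                   p1 = "numeric", p2 = "numeric"))

#' @describeIn ComparatorModel-class summary printout
#' @param object a comparator model
#' @export
setMethod("show", "ComparatorModel", function(object) {
    cat(sprintf("%s comparator (%s), %d-gene panel%s\n",
                toupper(object@kind), class(object),
                length(object@genePanel),
                if (isTRUE(object@panelFallback))
                    " [empty-filter fallback]" else ""))
})

#' Cross-validation / split-sample evaluation result
#'
#' Returned by [loocv()] and [evaluateSplit()]. Accuracy is overall percent
#' correct on held-out samples; per-class accuracies are kept for
#' diagnostics. \code{stability} maps each gene ever used by a fold's model
#' to the percentage of folds using it; for single-gene trainers these
#' percentages sum to 100.
#'
#' @slot scheme \code{"loocv"}, \code{"split1"} or \code{"split2"}.
#' @slot folds per-fold records: held-out sample ids, genes used, model
#'   summary, predicted and true labels.
#' @slot accuracyPct overall held-out accuracy, percent.
#' @slot perClassAccuracyPct named per-class accuracies, percent.
#' @slot meanGenesPerModel mean panel size across folds.
#' @slot stability named numeric, gene occurrence percentages, descending.
#' @slot seed random seed used (NA for the deterministic LOOCV scheme).
#' @export
setClass("EvaluationResult",
    representation(scheme = "character", folds = "list",
                   accuracyPct = "numeric", perClassAccuracyPct = "numeric",
                   meanGenesPerModel = "numeric", stability = "numeric",
                   seed = "integer"))

#' @describeIn EvaluationResult-class summary printout
#' @param object an \code{EvaluationResult}
#' @export
setMethod("show", "EvaluationResult", function(object) {
    cat(sprintf("EvaluationResult [%s], %d fold(s)\n",
                object@scheme, length(object@folds)))
    cat(sprintf("  accuracy: %.1f%%  (per class: %s)\n", object@accuracyPct,
                paste(sprintf("%s %.1f%%", names(object@perClassAccuracyPct),
                              object@perClassAccuracyPct), collapse = ", ")))
    cat(sprintf("  mean genes per model: %.2f\n", object@meanGenesPerModel))
    s <- object@stability
    if (length(s)) {
        top <- utils::head(s, 6L)
        cat("  gene stability:",
            paste(sprintf("%s (%.3g%%)", names(top), top), collapse = ", "))
        if (length(s) > 6L) cat(", ...")
        cat("\n")
    }
})

#' Dataset difficulty characterisation
#'
#' Summary statistics describing how separable a two-class dataset is: the
#' smallest univariate t-test p-value and its t-statistic, the largest
#' between-class mean fold change (linear scale, oriented >= 1), and the
#' number of genes significant at \code{alpha}.
#'
#' @slot smallestP smallest t-test p-value over genes.
#' @slot tStatistic signed t-statistic of that gene (printed as |t|).
#' @slot smallestPGene its gene identifier.
#' @slot maxFoldChange largest linear-scale fold change, >= 1.
#' @slot foldChangeGene gene attaining it.
#' @slot nSignificant genes with p < alpha.
#' @slot alpha the significance level used.
#' @slot scale \code{"linear"} or \code{"log2"} (input scale; log2 data are
#'   unlogged before fold-change computation).
#' @slot nExcluded genes excluded from fold-change ranking because a class
#'   mean was non-positive on the linear scale.
#' @export
setClass("CharacterizationReport",
    representation(smallestP = "numeric", tStatistic = "numeric",
                   smallestPGene = "character", maxFoldChange = "numeric",
                   foldChangeGene = "character", nSignificant = "integer",
                   alpha = "numeric", scale = "character",
                   nExcluded = "integer"))

#' @describeIn CharacterizationReport-class Table-style printout
#' @param object a \code{CharacterizationReport}
#' @export
setMethod("show", "CharacterizationReport", function(object) {
    cat("Dataset characterisation\n")
    cat(sprintf("  smallest p-value : %.3g  (gene %s)\n",
                object@smallestP, object@smallestPGene))
    cat(sprintf("  |t| at smallest p: %.2f\n", abs(object@tStatistic)))
    cat(sprintf("  max fold change  : %.4g  (gene %s, %s scale input)\n",
                object@maxFoldChange, object@foldChangeGene, object@scale))
    cat(sprintf("  # significant    : %d at alpha = %g\n",
                object@nSignificant, object@alpha))
    if (object@nExcluded > 0L)
        cat(sprintf("  (%d gene(s) excluded from fold change: non-positive class mean)\n",
                    object@nExcluded))
})
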