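#' @rdname accessors
#' @export
setMethod("exprValues", "TwoClassExpression", function(object)
    SummarizedExperiment::assay(object, "exprs"))

#' @rdname accessors
#' @export
setMethod("classLabels", "TwoClassExpression", function(object)
    SummarizedExperiment::colData(object)$class)

#' @rdname accessors
#' @export
setMethod("geneIds", "TwoClassExpression", function(object)
    rownames(object))

#' @rdname accessors
#' @export
setMethod("orderNumbers", "TwoClassExpression", function(object)
    SummarizedExperiment::rowData(object)$orderNumber)

#' @rdname accessors
#' @export
setMethod("classNames", "TwoClassExpression", function(object)
    levels(classLabels(object)))

#' @rdname accessors
#' @export
setMethod("genesUsed", "SGClassifier", function(object) object@geneId)

#' @rdname accessors
#' @export
setMethod("genesUsed", "ComparatorModel", function(object) object@genePanel)

# per-class sample counts of the observed labels
classCounts <- function(x) {
    tab <- table(classLabels(x))
    as.integer(tab[classNames(x)])
}

# guard used by all trainers: at least `min` samples in each class
checkTrainable <- function(x, min = 2L) {
    cc <- classCounts(x)
    if (any(cc < min))
        stop(sprintf("each class needs >= %d training samples (found %s)",
                     min, paste(classNames(x), cc, sep = "=",
                                collapse = ", ")))
    invisible(cc)
}
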