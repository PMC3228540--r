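#' Accessor generics
#'
#' Accessors for \linkS4class{TwoClassExpression} and the model classes.
#' \code{exprValues} returns the expression matrix, \code{classLabels} the
#' per-sample label factor (first level = class 1), \code{geneIds} /
#' \code{orderNumbers} the gene identifiers and their 0-based source-file
#' positions, \code{classNames} the two class levels, and \code{genesUsed}
#' the gene identifiers a fitted model actually consults at prediction time.
#'
#' @param object a \code{TwoClassExpression} or fitted model
#' @return see above
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("orderNumbers", function(object) standardGeneric("orderNumbers"))

#' @rdname accessors
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setGeneric("genesUsed", function(object) standardGeneric("genesUsed"))

#' @rdname geneStability
#' @export
setGeneric("geneStability", function(object) standardGeneric("geneStability"))
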