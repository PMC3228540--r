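#' Characterise dataset difficulty
#'
#' Computes the summary statistics that track how hard a two-class dataset
#' is to classify: the smallest univariate t-test p-value and the
#' corresponding t-statistic, the largest between-class mean fold change,
#' and the number of genes significant at \code{alpha} (default 0.001).
#'
#' Fold change is the ratio of class mean expressions on the linear scale,
#' oriented so it is always >= 1 (larger mean over smaller). Data on the
#' log2 scale are unlogged (2^x) before the means are taken; the scale is
#' never guessed — pass it explicitly. Genes with a non-positive linear
#' class mean have no meaningful ratio and are excluded from the
#' fold-change ranking with a warning.
#'
#' @inheritParams loocv
#' @param alpha significance level for the gene count (default 0.001)
#' @param scale input expression scale, \code{"linear"} or \code{"log2"}
#' @inheritParams scoreAllGenes
#' @return a \linkS4class{CharacterizationReport}
#' @examples
#' sim <- simulateTwoClassData(n1 = 15, n2 = 15, nGenes = 200,
#'                             nInformative = 1, effectSizes = 4, seed = 5)
#' characterize(sim$dataset, scale = "log2")
#' @export
characterize <- function(dataset, alpha = 0.001,
                         scale = c("linear", "log2"), varEqual = TRUE) {
    scale <- match.arg(scale)
    scores <- scoreAllGenes(dataset, method = "t", varEqual = varEqual)
    top <- scores[1L, ]
    nSig <- sum(scores$pValue < alpha & !scores$degenerate)

    X <- exprValues(dataset)
    if (scale == "log2") X <- 2^X
    lab <- classLabels(dataset)
    lv <- levels(lab)
    m1 <- rowMeans(X[, lab == lv[1], drop = FALSE])
    m2 <- rowMeans(X[, lab == lv[2], drop = FALSE])
    ok <- m1 > 0 & m2 > 0
    nExcluded <- sum(!ok)
    if (nExcluded > 0L)
        warning(sprintf("%d gene(s) excluded from fold change: non-positive linear-scale class mean",
                        nExcluded))
    if (!any(ok))
        stop("no gene has positive class means on the linear scale; fold change undefined")
    fc <- pmax(m1, m2)[ok] / pmin(m1, m2)[ok]
    imax <- which.max(fc)
    methods::new("CharacterizationReport",
                 smallestP = top$pValue, tStatistic = top$statistic,
                 smallestPGene = top$geneId,
                 maxFoldChange = unname(fc[imax]),
                 foldChangeGene = geneIds(dataset)[which(ok)[imax]],
                 nSignificant = as.integer(nSig), alpha = alpha,
                 scale = scale, nExcluded = as.integer(nExcluded))
}

#' Write a characterisation report as JSON
#'
#' The t-statistic is stored signed; the printed table shows its absolute
#' value.
#'
#' @param report a \linkS4class{CharacterizationReport}
#' @param path output file
#' @return the path, invisibly
#' @export
writeCharacterizationReport <- function(report, path) {
    obj <- list(schema_version = "1.0",
                smallest_p_value = report@smallestP,
                t_statistic = numJson(report@tStatistic),
                smallest_p_gene = report@smallestPGene,
                max_fold_change = report@maxFoldChange,
                fold_change_gene = report@foldChangeGene,
                n_significant = report@nSignificant,
                alpha = report@alpha, scale = report@scale,
                n_excluded_fold_change = report@nExcluded)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    invisible(path)
}
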