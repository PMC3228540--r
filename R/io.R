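#' Read a tab-delimited expression matrix with a class label file
#'
#' The matrix file is tab-delimited, UTF-8, "." decimal separator: a header
#' row of sample identifiers and a first column of gene identifiers. The
#' label file is tab-delimited with header columns \code{sample} and
#' \code{class}, mapping every matrix sample to one of exactly two class
#' names; label rows may be in any order (alignment is by sample id) and
#' extra samples in the label file are ignored. Class level order — hence
#' which class is class 1 — follows first appearance in the label file.
#' File row order is preserved as the genes' order numbers. Missing or
#' non-numeric cells are rejected with an error naming the offending
#' row and column.
#'
#' @param pathMatrix path to the expression matrix file
#' @param pathLabels path to the label file
#' @return a \linkS4class{TwoClassExpression}
#' @seealso [writeDataset()], [readGctCls()]
#' @export
readExpressionTSV <- function(pathMatrix, pathLabels) {
    raw <- utils::read.delim(pathMatrix, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "")
    if (ncol(raw) < 2L)
        stop(sprintf("'%s': need a gene-id column plus >= 1 sample column",
                     pathMatrix))
    gids <- raw[[1L]]
    sampleIds <- colnames(raw)[-1L]
    vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sampleIds))
    for (j in seq_along(sampleIds)) {
        col <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num))
        if (length(bad))
            stop(sprintf("'%s': non-numeric or missing value '%s' at gene '%s' (row %d), sample '%s'",
                         pathMatrix, col[bad[1L]], gids[bad[1L]], bad[1L],
                         sampleIds[j]))
        vals[, j] <- num
    }
    labs <- readLabelFile(pathLabels, sampleIds)
    TwoClassExpression(vals, labs, geneIds = gids, sampleIds = sampleIds,
                       metadata = list(sourceMatrix = pathMatrix,
                                       sourceLabels = pathLabels,
                                       format = "tsv"))
}

readLabelFile <- function(pathLabels, sampleIds) {
    lab <- utils::read.delim(pathLabels, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    if (!all(c("sample", "class") %in% colnames(lab)))
        stop(sprintf("'%s': label file needs 'sample' and 'class' columns",
                     pathLabels))
    m <- match(sampleIds, lab$sample)
    if (anyNA(m))
        stop(sprintf("samples missing from label file: %s",
                     paste(sampleIds[is.na(m)], collapse = ", ")))
    cls <- lab$class[m]
    uc <- unique(lab$class[sort(m)])    # level order: first appearance in file
    if (length(uc) != 2L)
        stop(sprintf("expected exactly 2 classes, found %d: %s",
                     length(uc), paste(uc, collapse = ", ")))
    factor(cls, levels = uc)
}

#' Read a GCT v1.2 expression file with a categorical CLS label file
#'
#' GCT v1.2: a "#1.2" line, a dimensions line, then a table with Name and
#' Description columns followed by one column per sample. Categorical CLS:
#' a counts line (\code{n 2 1}), a \code{# name1 name2} line, and a line of
#' per-sample class indices (0/1, mapped to the names in header order) or
#' class names. Labels are positional. The gene Description column is kept
#' in \code{rowData()$description}.
#'
#' @param pathGct path to the GCT file
#' @param pathCls path to the CLS file
#' @return a \linkS4class{TwoClassExpression}
#' @export
readGctCls <- function(pathGct, pathCls) {
    lines <- readLines(pathGct)
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
        stop(sprintf("'%s': not a GCT v1.2 file (missing '#1.2' header)",
                     pathGct))
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]),
                                                 "[ \t]+")[[1L]]))
    if (length(dims) != 2L || anyNA(dims))
        stop(sprintf("'%s': malformed dimensions line", pathGct))
    body <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                              sep = "\t", check.names = FALSE,
                              colClasses = "character", quote = "")
    if (nrow(body) != dims[1L])
        stop(sprintf("'%s': dimensions line declares %d genes but body has %d rows",
                     pathGct, dims[1L], nrow(body)))
    if (ncol(body) != dims[2L] + 2L)
        stop(sprintf("'%s': dimensions line declares %d samples but body has %d sample columns",
                     pathGct, dims[2L], ncol(body) - 2L))
    gids <- body[[1L]]
    desc <- body[[2L]]
    sampleIds <- colnames(body)[-(1:2)]
    vals <- matrix(NA_real_, nrow = nrow(body), ncol = length(sampleIds))
    for (j in seq_along(sampleIds)) {
        num <- suppressWarnings(as.numeric(body[[j + 2L]]))
        bad <- which(is.na(num))
        if (length(bad))
            stop(sprintf("'%s': non-numeric or missing value at gene '%s' (row %d), sample '%s'",
                         pathGct, gids[bad[1L]], bad[1L], sampleIds[j]))
        vals[, j] <- num
    }
    labs <- readClsFile(pathCls, length(sampleIds))
    x <- TwoClassExpression(vals, labs, geneIds = gids,
                            sampleIds = sampleIds,
                            metadata = list(sourceMatrix = pathGct,
                                            sourceLabels = pathCls,
                                            format = "gct"))
    SummarizedExperiment::rowData(x)$description <- desc
    x
}

readClsFile <- function(pathCls, nSamples) {
    cl <- readLines(pathCls)
    cl <- cl[nzchar(trimws(cl))]
    if (length(cl) < 3L)
        stop(sprintf("'%s': CLS file needs 3 lines", pathCls))
    hdr <- as.integer(strsplit(trimws(cl[1L]), "[ \t]+")[[1L]])
    names2 <- strsplit(trimws(cl[2L]), "[ \t]+")[[1L]]
    if (names2[1L] != "#")
        stop(sprintf("'%s': second CLS line must start with '#'", pathCls))
    classNames <- names2[-1L]
    if (length(classNames) != 2L || hdr[2L] != 2L)
        stop(sprintf("'%s': exactly 2 classes required", pathCls))
    toks <- strsplit(trimws(cl[3L]), "[ \t]+")[[1L]]
    if (hdr[1L] != nSamples || length(toks) != nSamples)
        stop(sprintf("'%s': CLS declares %d samples for a %d-sample matrix (%d assignment tokens)",
                     pathCls, hdr[1L], nSamples, length(toks)))
    idx <- suppressWarnings(as.integer(toks))
    cls <- if (!anyNA(idx)) {
        if (any(idx < 0L | idx > 1L))
            stop(sprintf("'%s': class indices must be 0 or 1", pathCls))
        classNames[idx + 1L]
    } else {
        if (!all(toks %in% classNames))
            stop(sprintf("'%s': unknown class name(s): %s", pathCls,
                         paste(setdiff(toks, classNames), collapse = ", ")))
        toks
    }
    factor(cls, levels = classNames)
}

#' Write a dataset to disk
#'
#' Writes the dataset in either dialect read by [readExpressionTSV()] /
#' [readGctCls()]. Values are printed with \code{\%.17g}, so a write/read
#' round trip reproduces them exactly, along with gene order numbers and
#' labels. Refuses to write a dataset with no genes.
#'
#' @param dataset a \linkS4class{TwoClassExpression}
#' @param stem output path stem; \code{"tsv"} writes \code{<stem>.tsv} and
#'   \code{<stem>_labels.tsv}, \code{"gct"} writes \code{<stem>.gct} and
#'   \code{<stem>.cls}
#' @param format \code{"tsv"} (default) or \code{"gct"}
#' @return character vector of the two file paths, invisibly
#' @export
writeDataset <- function(dataset, stem, format = c("tsv", "gct")) {
    format <- match.arg(format)
    if (nrow(dataset) == 0L)
        stop("refusing to write a dataset with no genes")
    X <- exprValues(dataset)
    fmtRow <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
    body <- vapply(seq_len(nrow(X)), function(i) fmtRow(X[i, ]),
                   character(1))
    lab <- classLabels(dataset)
    if (format == "tsv") {
        fMat <- paste0(stem, ".tsv"); fLab <- paste0(stem, "_labels.tsv")
        writeLines(c(paste(c("gene_id", colnames(X)), collapse = "\t"),
                     paste(rownames(X), body, sep = "\t")), fMat)
        # rows grouped by class level so the reader (level order = first
        # appearance) reconstructs the same class-1 designation
        ord <- order(as.integer(lab))
        writeLines(c("sample\tclass",
                     paste(colnames(X)[ord], as.character(lab)[ord],
                           sep = "\t")), fLab)
        return(invisible(c(fMat, fLab)))
    }
    fGct <- paste0(stem, ".gct"); fCls <- paste0(stem, ".cls")
    desc <- SummarizedExperiment::rowData(dataset)$description
    if (is.null(desc)) desc <- rownames(X)
    writeLines(c("#1.2",
                 paste(nrow(X), ncol(X), sep = "\t"),
                 paste(c("Name", "Description", colnames(X)),
                       collapse = "\t"),
                 paste(rownames(X), desc, body, sep = "\t")), fGct)
    lv <- levels(lab)
    writeLines(c(paste(ncol(X), 2, 1),
                 paste("#", lv[1], lv[2]),
                 paste(as.integer(lab) - 1L, collapse = " ")), fCls)
    invisible(c(fGct, fCls))
}
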