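test_that("TSV reader parses matrix + labels and preserves gene order", {
    d <- withr::local_tempdir()
    writeLines(c("gene_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t2\t3\t4",
                 "gB\t5\t6\t7\t8",
                 "gC\t9\t10\t11\t12"),
               file.path(d, "m.tsv"))
    writeLines(c("sample\tclass", "s1\tA", "s2\tA", "s3\tB", "s4\tB"),
               file.path(d, "lab.tsv"))
    x <- readExpressionTSV(file.path(d, "m.tsv"), file.path(d, "lab.tsv"))
    expect_identical(orderNumbers(x), 0:2)
    expect_identical(geneIds(x), c("gA", "gB", "gC"))
    expect_identical(classNames(x), c("A", "B"))
    expect_equal(exprValues(x)["gB", "s3"], 7)

    # labels aligned by sample id, not file row order
    writeLines(c("sample\tclass", "s4\tB", "s1\tA", "s3\tB", "s2\tA"),
               file.path(d, "lab2.tsv"))
    x2 <- readExpressionTSV(file.path(d, "m.tsv"), file.path(d, "lab2.tsv"))
    expect_identical(as.character(classLabels(x2)), c("A", "A", "B", "B"))
})

test_that("TSV reader rejects bad inputs with informative errors", {
    d <- withr::local_tempdir()
    writeLines(c("gene_id\ts1\ts2\ts3\ts4",
                 "gA\t1\t2\t3\t4", "gB\t5\t6\tx\t8"),
               file.path(d, "m.tsv"))
    writeLines(c("sample\tclass", "s1\tA", "s2\tA", "s3\tB", "s4\tC"),
               file.path(d, "lab3.tsv"))
    expect_error(
        readExpressionTSV(file.path(d, "m.tsv"), file.path(d, "lab3.tsv")),
        "non-numeric.*gB.*s3")
    writeLines(c("gene_id\ts1\ts2\ts3\ts4", "gA\t1\t2\t3\t4"),
               file.path(d, "ok.tsv"))
    expect_error(
        readExpressionTSV(file.path(d, "ok.tsv"), file.path(d, "lab3.tsv")),
        "3 classes|found 3")
    writeLines(c("sample\tclass", "s1\tA", "s2\tA", "s3\tB"),
               file.path(d, "short.tsv"))
    expect_error(
        readExpressionTSV(file.path(d, "ok.tsv"), file.path(d, "short.tsv")),
        "missing.*s4")
})

test_that("GCT/CLS reader handles the minimal dialect and its errors", {
    d <- withr::local_tempdir()
    writeLines(c("#1.2", "2\t3",
                 "Name\tDescription\ts1\ts2\ts3",
                 "gA\tdescA\t1.5\t2.5\t3.5",
                 "gB\tdescB\t4\t5\t6"),
               file.path(d, "x.gct"))
    writeLines(c("3 2 1", "# c1 c2", "0 0 1"), file.path(d, "x.cls"))
    x <- readGctCls(file.path(d, "x.gct"), file.path(d, "x.cls"))
    expect_identical(as.character(classLabels(x)), c("c1", "c1", "c2"))
    expect_identical(classNames(x), c("c1", "c2"))
    expect_identical(SummarizedExperiment::rowData(x)$description,
                     c("descA", "descB"))

    writeLines(c("#1.2", "5\t3",
                 "Name\tDescription\ts1\ts2\ts3",
                 "gA\tdescA\t1.5\t2.5\t3.5",
                 "gB\tdescB\t4\t5\t6"),
               file.path(d, "bad.gct"))
    expect_error(readGctCls(file.path(d, "bad.gct"), file.path(d, "x.cls")),
                 "declares 5 genes")
    writeLines(c("4 2 1", "# c1 c2", "0 0 1 1"), file.path(d, "bad.cls"))
    expect_error(readGctCls(file.path(d, "x.gct"), file.path(d, "bad.cls")),
                 "declares 4 samples")
})

test_that("write -> read round trip is the identity for both dialects", {
    sim <- simulateTwoClassData(n1 = 4, n2 = 5, nGenes = 12, seed = 42)
    # permuted labels stress class-level-order preservation
    x <- permuteClassLabels(sim$dataset, seed = 9)
    d <- withr::local_tempdir()
    for (fmt in c("tsv", "gct")) {
        files <- writeDataset(x, file.path(d, fmt), format = fmt)
        y <- if (fmt == "tsv") readExpressionTSV(files[1], files[2])
             else readGctCls(files[1], files[2])
        expect_identical(exprValues(y), exprValues(x), info = fmt)
        expect_identical(geneIds(y), geneIds(x), info = fmt)
        expect_identical(orderNumbers(y), orderNumbers(x), info = fmt)
        expect_identical(classLabels(y), classLabels(x), info = fmt)
    }
})

test_that("writeDataset refuses no genes but accepts 1 sample per class", {
    sim <- simulateTwoClassData(n1 = 3, n2 = 3, nGenes = 5, seed = 1)
    d <- withr::local_tempdir()
    expect_error(writeDataset(sim$dataset[0, ], file.path(d, "empty")),
                 "no genes")
    tiny <- makeDataset(matrix(1:4, 2), c("a", "b"))
    expect_silent(writeDataset(tiny, file.path(d, "tiny")))
    back <- readExpressionTSV(file.path(d, "tiny.tsv"),
                              file.path(d, "tiny_labels.tsv"))
    expect_identical(exprValues(back), exprValues(tiny))
})

test_that("downstream statistics are invariant to sample column order", {
    sim <- simulateTwoClassData(n1 = 6, n2 = 6, nGenes = 30,
                                nInformative = 2, effectSizes = c(2, 3),
                                seed = 8)
    x <- sim$dataset
    perm <- c(5, 1, 12, 3, 7, 9, 2, 11, 4, 10, 6, 8)
    y <- x[, perm]
    for (m in c("t", "wmw")) {
        sx <- scoreAllGenes(x, m); sy <- scoreAllGenes(y, m)
        expect_identical(sx$geneId, sy$geneId)
        expect_equal(sx$pValue, sy$pValue)
    }
    expect_equal(trainSGC(x)@cutPoint, trainSGC(y)@cutPoint)
})

test_that("constructor enforces the two-class and uniqueness invariants", {
    m <- matrix(1:6, 2)
    expect_error(TwoClassExpression(m, c("a", "b", "c")), "2 classes")
    expect_error(TwoClassExpression(m, c("a", "a", "a")), "2 classes")
    expect_error(TwoClassExpression(m, c("a", "a", "b"),
                                    sampleIds = c("s", "s", "t")),
                 "unique")
    m[1] <- NA
    expect_error(TwoClassExpression(m, c("a", "a", "b")), "missing")
})
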