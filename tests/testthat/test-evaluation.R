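# trainer that ignores its training data and always predicts `cls`
constantTrainer <- function(cls, other, lv) {
    function(dataset)
        new("SGClassifier", geneId = geneIds(dataset)[1],
            orderNumber = orderNumbers(dataset)[1], method = "t",
            cutPoint = 1e300, direction = "leq_is_c1",
            classes = c(cls, other), classLevels = lv,
            trainingStats = list(statistic = 0, pValue = 1, entropy = 1,
                                 candidateCount = 0L, fallbackUsed = FALSE,
                                 n1 = 1L, n2 = 1L,
                                 trainingAccuracyPct = 50, varEqual = TRUE,
                                 exactLimit = 20L))
}

test_that("LOOCV on a separable dataset is perfect and fully stable", {
    sim <- simulateTwoClassData(n1 = 20, n2 = 20, nGenes = 50,
                                nInformative = 1, effectSizes = 8,
                                seed = 6)
    res <- loocv(sim$dataset, sgcTrainer("t"))
    expect_identical(length(res@folds), 40L)
    expect_identical(sort(vapply(res@folds, `[[`, "", "heldOut")),
                     sort(colnames(sim$dataset)))
    expect_identical(res@accuracyPct, 100)
    expect_identical(res@meanGenesPerModel, 1)
    expect_identical(geneStability(res),
                     setNames(100, sim$truth$informativeGenes))
})

test_that("single-gene trainers always use exactly one gene per fold", {
    x <- noiseDataset(40, 6, 6, seed = 2)
    for (m in c("t", "wmw")) {
        res <- loocv(x, sgcTrainer(m))
        expect_identical(res@meanGenesPerModel, 1)
        expect_equal(sum(geneStability(res)), 100)
    }
})

test_that("LOOCV with a constant classifier scores the class proportion", {
    x <- noiseDataset(20, 9, 5, seed = 4)
    lv <- classNames(x)
    res <- loocv(x, constantTrainer(lv[1], lv[2], lv))
    expect_equal(res@accuracyPct, 100 * 9 / 14)
    res2 <- loocv(x, constantTrainer(lv[2], lv[1], lv))
    expect_equal(res2@accuracyPct, 100 * 5 / 14)
})

test_that("per-fold selection inside LOOCV matches manual re-selection", {
    sim <- simulateTwoClassData(n1 = 8, n2 = 8, nGenes = 50,
                                nInformative = 1, effectSizes = 1.5,
                                seed = 10)
    x <- sim$dataset
    res <- loocv(x, sgcTrainer("t"))
    set.seed(1)
    for (i in sample(ncol(x), 4)) {
        manual <- selectTopGene(x[, -i], "t")
        expect_identical(res@folds[[i]]$genes, manual$geneId)
    }
})

test_that("sample order changes nothing but fold order", {
    sim <- simulateTwoClassData(n1 = 6, n2 = 6, nGenes = 30,
                                nInformative = 1, effectSizes = 2,
                                seed = 15)
    x <- sim$dataset
    perm <- c(7, 2, 11, 4, 1, 9, 12, 3, 8, 5, 10, 6)
    r1 <- loocv(x, sgcTrainer("t"))
    r2 <- loocv(x[, perm], sgcTrainer("t"))
    expect_identical(r1@accuracyPct, r2@accuracyPct)
    expect_identical(geneStability(r1), geneStability(r2))
})

test_that("LOOCV refuses datasets where a fold would break a class", {
    x <- makeDataset(matrix(rnorm(20), 4), c("a", "a", "b", "b", "b"))
    expect_error(loocv(x, sgcTrainer("t")), "split")
})

test_that("stratified splits follow the type 1 / type 2 arithmetic", {
    sim1 <- simulateTwoClassData(n1 = 50, n2 = 50, nGenes = 5, seed = 1)
    sp <- splitSample(sim1$dataset, "type1", seed = 11)
    expect_identical(table(classLabels(sp$train)),
                     table(classLabels(sp$test)))
    expect_identical(ncol(sp$train), 50L)

    sim2 <- simulateTwoClassData(n1 = 46, n2 = 14, nGenes = 5, seed = 2)
    sp2 <- splitSample(sim2$dataset, "type2", seed = 12)
    tabTr <- table(classLabels(sp2$train))
    expect_identical(as.integer(tabTr), c(31L, 10L))   # ceil(2/3 per class)
    expect_identical(as.integer(table(classLabels(sp2$test))), c(15L, 4L))

    # determinism: same seed, same split; train/test are a partition
    sp2b <- splitSample(sim2$dataset, "type2", seed = 12)
    expect_identical(colnames(sp2b$train), colnames(sp2$train))
    sp2c <- splitSample(sim2$dataset, "type2", seed = 13)
    expect_false(identical(colnames(sp2c$train), colnames(sp2$train)))
    expect_identical(sort(c(colnames(sp2$train), colnames(sp2$test))),
                     sort(colnames(sim2$dataset)))

    tiny <- simulateTwoClassData(n1 = 3, n2 = 2, nGenes = 5, seed = 3)
    expect_error(splitSample(tiny$dataset, "type2", seed = 1), "< 2 samples")
})

test_that("split evaluation: self-consistency and degenerate test sets", {
    sim <- simulateTwoClassData(n1 = 10, n2 = 10, nGenes = 80,
                                nInformative = 1, effectSizes = 2.5,
                                seed = 30)
    x <- sim$dataset
    m <- trainSGC(x)
    res <- evaluateSplit(x, x, sgcTrainer("t"))
    expect_equal(res@accuracyPct, m@trainingStats$trainingAccuracyPct)

    one <- evaluateSplit(x, x[, 1], sgcTrainer("t"))
    expect_true(one@accuracyPct %in% c(0, 100))

    expect_error(evaluateSplit(x, x[1:50, ], sgcTrainer("t")),
                 "panel mismatch")
})

test_that("split-sample accuracy approaches the planted Bayes accuracy", {
    sim <- simulateTwoClassData(n1 = 40, n2 = 40, nGenes = 200,
                                nInformative = 1, effectSizes = 3,
                                seed = 55)
    accs <- vapply(1:20, function(s) {
        sp <- splitSample(sim$dataset, "type1", seed = s)
        evaluateSplit(sp$train, sp$test, sgcTrainer("t"),
                      scheme = "split1", seed = s)@accuracyPct
    }, numeric(1))
    expect_gte(mean(accs), 90)     # Bayes accuracy is 100 * pnorm(1.5) ~ 93.3
})

test_that("evaluation reports serialize to JSON", {
    sim <- simulateTwoClassData(n1 = 5, n2 = 5, nGenes = 20,
                                nInformative = 1, effectSizes = 4, seed = 9)
    res <- loocv(sim$dataset, sgcTrainer("t"))
    path <- withr::local_tempfile(fileext = ".json")
    writeEvaluationReport(res, path)
    rep <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_identical(rep$scheme, "loocv")
    expect_equal(rep$accuracy_pct, res@accuracyPct)
    expect_equal(rep$mean_genes_per_model, 1)
    expect_equal(sum(rep$stability$occurrence_pct), 100)
})
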