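# linear-scale dataset with one gene crossing the background level: the
# "easy" regime in which every classifier should succeed
overwhelmingGeneDataset <- function(n1 = 20, n2 = 20, nGenes = 50,
                                    seed = 1234) {
    set.seed(seed)
    vals <- matrix(rnorm(nGenes * (n1 + n2), mean = 8, sd = 1), nGenes)
    vals[7, ] <- c(rnorm(n1, mean = 1, sd = 0.2),
                   rnorm(n2, mean = 150, sd = 2))   # fold change ~150
    makeDataset(vals, rep(c("a", "b"), c(n1, n2)))
}

test_that("DLDA: separation, closed-form boundary and tie behaviour", {
    x <- overwhelmingGeneDataset()
    m <- trainDLDA(x)
    expect_identical(as.character(predict(m, x)),
                     as.character(classLabels(x)))

    # two genes, exact means +/-1, shared variance: boundary is sum(x) = 0
    tr <- cbind(c(0, 2), c(2, 0), c(1, 1), c(0, -2), c(-2, 0), c(-1, -1))
    xt <- makeDataset(tr, rep(c("p", "n"), each = 3))
    md <- trainDLDA(xt, alpha = 0.999)
    expect_identical(length(md@genePanel), 2L)
    query <- cbind(c(3, 1), c(-0.5, -1), c(2, -3), c(0.25, 0.5))
    xq <- makeDataset(query, c("p", "p", "n", "n"))
    got <- as.character(predict(md, xq))
    expect_identical(got, ifelse(colSums(query) > 0, "p", "n"))
    # equidistant query: tie goes to class 1
    x0 <- makeDataset(cbind(c(0, 0), c(9, 9)), c("p", "n"))
    expect_identical(as.character(predict(md, x0))[1], "p")
})

test_that("DLDA floors zero-variance genes instead of dividing by zero", {
    vals <- rbind(c(1, 1, 1, 2, 2, 2),       # zero within-class variance
                  c(0.1, 0.2, 0.3, 5.1, 5.2, 5.3))
    x <- makeDataset(vals, rep(c("a", "b"), each = 3))
    expect_warning(m <- trainDLDA(x, alpha = 0.5), "floored")
    expect_identical(as.character(predict(m, x)),
                     as.character(classLabels(x)))
})

test_that("k-NN matches an exhaustive neighbour-search oracle", {
    x <- overwhelmingGeneDataset()
    m3 <- trainKNN(x)
    expect_identical(as.character(predict(m3, x)),
                     as.character(classLabels(x)))
    m1 <- trainKNN(x, k = 1)
    expect_identical(as.character(predict(m1, x[, 5])),
                     as.character(classLabels(x))[5])

    set.seed(404)
    for (i in 1:20) {
        tr <- matrix(rnorm(3 * 12), 3)
        xt <- makeDataset(tr, rep(c("a", "b"), each = 6))
        mt <- trainKNN(xt, alpha = 1 - 1e-12, k = 3)
        q <- matrix(rnorm(3 * 5), 3)
        xq <- makeDataset(q, c("a", "a", "a", "b", "b"))
        idx <- match(mt@panelOrder, orderNumbers(xt))
        oracle <- apply(q[idx, , drop = FALSE], 2, function(v) {
            d <- sqrt(colSums((tr[idx, , drop = FALSE] - v)^2))
            nb <- order(d)[1:3]
            names(which.max(table(as.character(classLabels(xt))[nb])))
        })
        expect_identical(as.character(predict(mt, xq)), unname(oracle))
    }
})

test_that("linear SVM separates, respects the 1-D threshold, flips with labels", {
    x <- overwhelmingGeneDataset()
    ms <- trainSVMLinear(x)
    expect_identical(as.character(predict(ms, x)),
                     as.character(classLabels(x)))

    # 1-gene panel: decision threshold lies between the class supports
    x1 <- makeDataset(matrix(c(1, 2, 4, 5), 1), c("lo", "lo", "hi", "hi"))
    m1 <- trainSVMLinear(x1, alpha = 0.999, cost = 100)
    expect_identical(as.character(predict(m1, makeDataset(
        matrix(c(1.9, 2.9, 3.1, 4.1), 1), c("lo", "lo", "hi", "hi")))),
        c("lo", "lo", "hi", "hi"))

    # flipping all labels flips all predictions
    xf <- makeDataset(exprValues(x),
                      ifelse(classLabels(x) == "a", "b", "a"),
                      geneIds = geneIds(x), sampleIds = colnames(x))
    mf <- trainSVMLinear(xf)
    pf <- as.character(predict(mf, x))
    ps <- as.character(predict(ms, x))
    expect_true(all(pf != ps))
})

test_that("random forest: signal recovery and seeded determinism", {
    x <- overwhelmingGeneDataset()
    m <- trainRF(x, seed = 77)
    expect_gte(100 * mean(predict(m, x) == classLabels(x)), 95)
    m2 <- trainRF(x, seed = 77)
    expect_identical(predict(m2, x), predict(m, x))
    mOne <- trainRF(x, nTrees = 1, seed = 5)
    expect_s4_class(mOne, "RFModel")
    expect_identical(length(predict(mOne, x)), ncol(x))
})

test_that("TSP matches the brute-force pair oracle and is rank-invariant", {
    set.seed(909)
    for (i in 1:5) {
        vals <- matrix(rnorm(20 * 14), 20)
        vals[3, 8:14] <- vals[3, 8:14] + 2.5
        x <- makeDataset(vals, rep(c("a", "b"), c(7, 7)))
        m <- trainTSP(x)

        bestDelta <- 0
        for (gi in 1:19) for (gj in (gi + 1):20) {
            p1 <- mean(vals[gi, 1:7] < vals[gj, 1:7])
            p2 <- mean(vals[gi, 8:14] < vals[gj, 8:14])
            bestDelta <- max(bestDelta, abs(p1 - p2))
        }
        expect_equal(m@delta, bestDelta)

        # strictly increasing transform: same pair, same predictions
        xT <- makeDataset(exp(vals), rep(c("a", "b"), c(7, 7)))
        mT <- trainTSP(xT)
        expect_identical(mT@genePanel, m@genePanel)
        expect_identical(predict(mT, xT), predict(m, x))
    }
})

test_that("a perfectly reversing pair gives delta 1 and perfect training", {
    vals <- rbind(c(1, 1, 1, 5, 5, 5),
                  c(3, 3, 3, 3, 3, 3),
                  c(0.5, 0.4, 0.6, 0.5, 0.6, 0.4))
    x <- makeDataset(vals, rep(c("a", "b"), each = 3))
    m <- trainTSP(x)
    expect_identical(m@delta, 1)
    expect_identical(as.character(predict(m, x)),
                     as.character(classLabels(x)))
    flat <- makeDataset(matrix(c(1, 2), 2, 6)[, 1:6, drop = FALSE],
                        rep(c("a", "b"), each = 3))
    expect_error(trainTSP(flat), "no discriminative pair")
})

test_that("empty significance filter falls back to the top gene", {
    x <- noiseDataset(100, 6, 6, seed = 3)
    sig <- significantGenes(x, alpha = 1e-6)
    expect_identical(nrow(sig), 0L)
    m <- trainDLDA(x, alpha = 1e-6)
    expect_true(m@panelFallback)
    expect_identical(length(m@genePanel), 1L)
    expect_identical(m@genePanel, selectTopGene(x, "t")$geneId)

    easy <- overwhelmingGeneDataset()
    expect_false(trainDLDA(easy)@panelFallback)
})

test_that("every classifier handles the overwhelming-gene regime", {
    x <- overwhelmingGeneDataset(n1 = 20, n2 = 20)
    trainers <- list(sgc_t = sgcTrainer("t"), sgc_w = sgcTrainer("wmw"),
                     dlda = dldaTrainer(), knn = knnTrainer(),
                     svm = svmTrainer(), rf = rfTrainer(seed = 9),
                     tsp = tspTrainer())
    for (nm in names(trainers)) {
        res <- loocv(x, trainers[[nm]])
        expect_gte(res@accuracyPct, 95)
    }
})

test_that("comparator JSON round trip (DLDA, kNN, TSP)", {
    x <- overwhelmingGeneDataset(n1 = 8, n2 = 8, nGenes = 15)
    for (m in list(trainDLDA(x), trainKNN(x), trainTSP(x))) {
        path <- withr::local_tempfile(fileext = ".json")
        writeModel(m, path)
        m2 <- readModel(path)
        expect_identical(predict(m2, x), predict(m, x))
    }
})
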