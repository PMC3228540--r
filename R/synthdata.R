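#' Simulate a two-class expression dataset with known ground truth
#'
#' Seeded generator of Gaussian two-class expression data emulating the
#' regimes bulk expression studies span: easy datasets with strongly
#' shifted genes, hard datasets with few or no informative genes, small or
#' imbalanced sample sizes, and heavy-tailed contamination that stresses
#' the t-test's outlier sensitivity against the rank test's robustness.
#'
#' Background genes are i.i.d. Normal(baseMean, baseSd^2) in both classes.
#' Each informative gene has its class-2 mean shifted by
#' \code{effectSizes[g] * baseSd} (effect sizes are in within-class SD
#' units). Under \code{noiseModel = "contaminated"} each matrix cell is,
#' independently with probability \code{contamRate}, drawn with its noise
#' SD inflated by \code{contamScale} (class means untouched, so
#' contamination adds symmetric heavy tails rather than signal).
#'
#' Ground truth carries, per informative gene, the Bayes-optimal cut point
#' (midpoint of the class means) and the single-gene Bayes accuracy
#' \eqn{\Phi(\delta/2)}, so achieved accuracy can be compared with the
#' optimum rather than an arbitrary threshold.
#'
#' @param n1,n2 samples in class 1 / class 2 (default 20 each)
#' @param nGenes total genes (default 1000)
#' @param nInformative number of shifted genes (default 1; 0 gives pure
#'   noise)
#' @param effectSizes per-informative-gene mean shift in SD units
#'   (recycled; default 3)
#' @param baseMean,baseSd background Gaussian parameters (default 8 and 1,
#'   log2-intensity-like)
#' @param noiseModel \code{"gaussian"} or \code{"contaminated"}
#' @param contamRate,contamScale contamination probability per cell and SD
#'   inflation factor (defaults 0.1 and 10)
#' @param scale scale tag recorded in metadata (\code{"log2"} default)
#' @param classNames the two class labels (class 1 first)
#' @param seed integer seed, mandatory
#' @return list with \code{dataset} (a \linkS4class{TwoClassExpression};
#'   samples of class 1 first) and \code{truth}: informative gene ids and
#'   1-based row indices, effect sizes, Bayes cut points and Bayes
#'   accuracies
#' @examples
#' sim <- simulateTwoClassData(seed = 1)
#' sim$truth$informativeGenes
#' selectTopGene(sim$dataset)$geneId
#' @export
simulateTwoClassData <- function(n1 = 20L, n2 = 20L, nGenes = 1000L,
                                 nInformative = 1L, effectSizes = 3,
                                 baseMean = 8, baseSd = 1,
                                 noiseModel = c("gaussian", "contaminated"),
                                 contamRate = 0.1, contamScale = 10,
                                 scale = c("log2", "linear"),
                                 classNames = c("c1", "c2"), seed) {
    noiseModel <- match.arg(noiseModel)
    scale <- match.arg(scale)
    stopifnot(n1 >= 1L, n2 >= 1L, nGenes >= 1L,
              nInformative >= 0L, nInformative <= nGenes,
              baseSd > 0, contamRate >= 0, contamRate <= 1,
              contamScale >= 1, length(classNames) == 2L)
    if (missing(seed)) stop("a seed is mandatory")
    effectSizes <- rep_len(as.numeric(effectSizes), nInformative)
    n <- n1 + n2
    sim <- withSeed(seed, {
        informative <- if (nInformative > 0L)
            sort(sample.int(nGenes, nInformative)) else integer(0)
        noise <- matrix(stats::rnorm(nGenes * n, 0, baseSd), nGenes, n)
        if (noiseModel == "contaminated") {
            hit <- matrix(stats::runif(nGenes * n) < contamRate, nGenes, n)
            noise[hit] <- stats::rnorm(sum(hit), 0, contamScale * baseSd)
        }
        list(informative = informative, noise = noise)
    })
    means <- matrix(baseMean, nGenes, n)
    if (nInformative > 0L)
        means[sim$informative, n1 + seq_len(n2)] <-
            baseMean + effectSizes * baseSd
    vals <- means + sim$noise
    gids <- sprintf("g%04d", seq_len(nGenes))
    sids <- sprintf("s%03d", seq_len(n))
    labels <- factor(rep(classNames, c(n1, n2)), levels = classNames)
    dataset <- TwoClassExpression(vals, labels, geneIds = gids,
        sampleIds = sids,
        metadata = list(scale = scale, seed = seed,
                        noiseModel = noiseModel,
                        config = list(n1 = n1, n2 = n2, nGenes = nGenes,
                                      nInformative = nInformative,
                                      effectSizes = effectSizes,
                                      baseMean = baseMean, baseSd = baseSd,
                                      contamRate = contamRate,
                                      contamScale = contamScale)))
    truth <- list(informativeGenes = gids[sim$informative],
                  informativeRows = sim$informative,
                  effectSizes = effectSizes,
                  bayesCutPoints = baseMean + effectSizes * baseSd / 2,
                  bayesAccuracy = stats::pnorm(effectSizes / 2))
    list(dataset = dataset, truth = truth)
}

#' Permute class labels (null datasets)
#'
#' Returns the dataset with its labels permuted uniformly at random; the
#' expression matrix and the class sizes are untouched. Used to build
#' label-permutation null distributions.
#'
#' @inheritParams loocv
#' @param seed integer seed
#' @return a \linkS4class{TwoClassExpression}
#' @export
permuteClassLabels <- function(dataset, seed) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    lab <- classLabels(dataset)
    perm <- withSeed(seed, sample(seq_along(lab)))
    SummarizedExperiment::colData(dataset)$class <- lab[perm]
    dataset
}
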