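#' Entropy-based optimal cut point for a single gene
#'
#' The classifier's core discretisation step. Samples are sorted by
#' expression (stable: original order breaks ties); the candidate cut point
#' set is the midpoints between consecutive sorted samples whose class
#' labels differ. Each candidate t splits the training set into
#' \eqn{S_1 = \{s : E(g,s) \le t\}} and its complement, and the candidate
#' minimising the class information entropy of that partition is the cut
#' point (entropy ties go to the smallest t). When the candidate set is
#' empty (constant expression) the mean expression is used and
#' \code{fallbackUsed} is set.
#'
#' With tied expression values spanning the class boundary, the midpoint of
#' a tied pair equals the shared value; because the decision rule uses
#' \code{<= t}, a cut at a tied value places every tied sample on the
#' left-hand side. Candidates at or above the maximum expression would
#' induce a trivial partition (empty right-hand side) and are excluded, so
#' a constant gene yields an empty candidate set and the mean fallback.
#'
#' @param expr numeric expression values of one gene, one per sample
#' @param labels two-level factor of class labels aligned with \code{expr};
#'   the first level is class 1
#' @param t a finite threshold
#'
#' @return \code{candidateCutPoints}: ascending numeric vector (possibly
#'   empty). \code{partitionEntropy}: the weighted conditional class
#'   entropy in bits, in [0, 1] for two classes. \code{ruleDirection}:
#'   \code{"leq_is_c1"} if assigning class 1 to the \code{<= t} side
#'   classifies strictly more training samples correctly than incorrectly,
#'   else \code{"leq_is_c2"} (an exact tie reverses). \code{optimalCutPoint}:
#'   list with \code{cutPoint}, \code{entropy}, \code{direction},
#'   \code{candidateCount}, \code{fallbackUsed}.
#'
#' @examples
#' optimalCutPoint(c(1, 2, 3, 4), factor(c("a", "a", "b", "b")))
#' @export
candidateCutPoints <- function(expr, labels) {
    labels <- as.factor(labels)
    stopifnot(length(expr) == length(labels))
    n <- length(expr)
    if (n < 2L) return(numeric(0))
    ord <- order(expr)                       # stable radix sort
    e <- expr[ord]; l <- labels[ord]
    boundary <- l[-n] != l[-1L]
    mids <- (e[-n] + e[-1L])[boundary] / 2
    mids <- mids[mids < e[n]]        # drop trivial (empty-side) partitions
    sort(unique(mids))
}

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

#' @rdname candidateCutPoints
#' @export
partitionEntropy <- function(expr, labels, t) {
    labels <- as.factor(labels)
    stopifnot(length(expr) == length(labels), is.finite(t))
    lv <- levels(labels)
    n <- length(expr)
    s1 <- expr <= t
    p11 <- sum(s1 & labels == lv[1]); p12 <- sum(s1) - p11
    p21 <- sum(!s1 & labels == lv[1]); p22 <- sum(!s1) - p21
    side <- function(a, b) {
        m <- a + b
        if (m == 0L) return(0)
        -(m / n) * (plogp(a / m) + plogp(b / m))
    }
    side(p11, p12) + side(p21, p22) + 0   # + 0 normalises IEEE -0
}

#' @rdname candidateCutPoints
#' @export
ruleDirection <- function(expr, labels, t) {
    labels <- as.factor(labels)
    stopifnot(is.finite(t))
    lv <- levels(labels)
    s1 <- expr <= t
    correct <- sum(s1 & labels == lv[1]) + sum(!s1 & labels == lv[2])
    incorrect <- length(expr) - correct
    if (correct > incorrect) "leq_is_c1" else "leq_is_c2"
}

#' @rdname candidateCutPoints
#' @export
optimalCutPoint <- function(expr, labels) {
    labels <- as.factor(labels)
    if (nlevels(droplevels(labels)) != 2L)
        stop("both classes must be present")
    P <- candidateCutPoints(expr, labels)
    if (length(P) == 0L) {
        cut <- mean(expr)
        fallback <- TRUE
        ent <- partitionEntropy(expr, labels, cut)
    } else {
        ents <- vapply(P, function(t) partitionEntropy(expr, labels, t),
                       numeric(1))
        i <- which.min(ents)                 # first minimum = smallest t
        cut <- P[i]; ent <- ents[i]
        fallback <- FALSE
    }
    list(cutPoint = cut, entropy = ent,
         direction = ruleDirection(expr, labels, cut),
         candidateCount = length(P), fallbackUsed = fallback)
}
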