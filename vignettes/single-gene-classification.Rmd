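---
title: "Single-gene classification of two-class expression data"
author: "sgclass maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-gene classification of two-class expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgclass)
```

## The problem

Most expression-based classifiers of tumour class, prognosis or treatment
response combine tens to thousands of genes. That costs interpretability and
makes migration to targeted clinical assays hard. `sgclass` implements the
opposite extreme: a classifier built on a *single* gene with a *single*
expression threshold, developed and evaluated with enough care that its
honest accuracy can be compared against multi-gene standards (DLDA, k-NN,
linear SVM, random forest, the top-scoring-pair rule).

## The model

Training data are a gene-by-sample matrix $E(g, s)$ with a binary class
label $C(s) \in \{c_1, c_2\}$ per sample. Development has three steps, all
repeated from scratch on every training set handed to the trainer.

**1. Gene selection.** Every gene is scored with a two-sided two-sample
test: the pooled-variance t-test (`method = "t"`) or the
Wilcoxon–Mann–Whitney rank-sum test (`method = "wmw"`). The gene with the
smallest p-value is selected; if several genes tie exactly, the one with
the smallest *order number* (0-based row position in the source file) wins,
making selection fully deterministic. The WMW option exists because the
t-statistic is fragile under gross errors; ranks are not.

**2. Cut point by entropy minimisation.** Samples are sorted by the
selected gene's expression (stable sort; original order breaks ties). The
candidate set $P$ contains the midpoints of consecutive sorted samples
whose classes differ. Each candidate $t$ splits the training set $S$ into
$S_1 = \{s : E(g,s) \le t\}$ and $S_2 = S \setminus S_1$, and is scored by
the class information entropy

$$E(g,t,S) = -\frac{|S_1|}{|S|}\sum_{j=1,2}\frac{|P_{1j}|}{|S_1|}\log_2\frac{|P_{1j}|}{|S_1|}
            -\frac{|S_2|}{|S|}\sum_{j=1,2}\frac{|P_{2j}|}{|S_2|}\log_2\frac{|P_{2j}|}{|S_2|},$$

where $P_{ij}$ is the intersection of $S_i$ with true class $c_j$ and
$0\log_2 0 \equiv 0$. The minimising candidate is the cut point $T$
(entropy ties go to the smallest $t$). If $P$ is empty, $T$ falls back to
the mean expression of the gene.

**3. Direction.** The default rule is $E(g,s) \le T \Rightarrow c_1$. If
it classifies at most as many training samples correctly as incorrectly
($|P_{11}|+|P_{22}| \le |P_{12}|+|P_{21}|$), the direction is reversed —
note the tie *reverses*. Consequently training accuracy is at least 50% by
construction.

## Evaluation

`loocv()` implements *complete* leave-one-out cross-validation: for each
held-out sample the entire development — selection, cut point, direction,
and for comparators the significance filter — is re-run on the remaining
$n-1$ samples. Nothing fitted on the full data ever touches a held-out
prediction; a test re-derives fold selections independently to prove it.
`splitSample()` provides the two split-sample designs (train:test about
1:1, "type 1", and about 2:1, "type 2"), stratified by class with the
training share rounded up per class. Whether the original split designs
were stratified is not documented anywhere we know of; stratification was
chosen because unstratified splits at these sample sizes can produce test
sets missing a class entirely.

Reports carry overall percent correct (the headline metric), per-class
accuracies (diagnostics), the mean number of genes per fold model, and the
*stability table*: the percentage of folds in which each gene was used.
For single-gene trainers the stability percentages sum to 100 and directly
measure how reproducible the selection is.

## Comparators

All comparators except TSP are preceded by a univariate t-test filter at
`alpha = 0.001` (strict inequality), re-run inside every fold. Settings
follow common practice for this problem class: k-NN with $k=3$ and
Euclidean distance; linear-kernel soft-margin SVM with cost 1; random
forest with 100 trees and $\lfloor\sqrt{p}\rfloor$ candidate genes per
split (the only stochastic comparator — it requires an explicit seed);
DLDA with per-gene class means and pooled per-gene variances. The
top-scoring-pair rule is implemented in its classical single-pair form,
scored by the between-class difference in within-sample ordering
frequency, with the mean rank-difference as secondary tie-break; being
rank-based it takes no filter. When the filter returns no gene the
comparators fall back to the single smallest-p gene rather than failing —
real panels this small do occur on hard datasets.

## The synthetic-data generator

`simulateTwoClassData()` produces the regimes the methods are designed to
span. Background genes are i.i.d. Normal(`baseMean`, `baseSd`^2) in both
classes (defaults 8 and 1, resembling log2 intensities); informative genes
shift the class-2 mean by `effectSizes` standard deviations; the
`contaminated` noise model inflates each cell's noise SD by `contamScale`
with probability `contamRate` (defaults 10 and 0.1), adding symmetric
heavy tails without moving class means — the regime where rank-based
selection should beat the t-test. Ground truth includes each informative
gene's Bayes-optimal cut point (class-mean midpoint) and its single-gene
Bayes accuracy $\Phi(\delta/2)$, so tests compare achieved accuracy to the
optimum instead of an arbitrary bar.

What the generator does *not* emulate: gene–gene correlation, multiplicative
(linear-scale) fold-change structure, batch effects, and non-Gaussian
marginals beyond the contamination model. Passing tests therefore
demonstrate correctness of the algorithms and calibration under idealised
conditions, not performance claims about any particular real dataset.

## Numerical and design choices

* **Default t-test is pooled-variance** (the era's standard for this
  analysis); Welch is available via `varEqual = FALSE`. Two-sided
  p-values throughout.
* **WMW branches** at a pooled sample size of 20: exact null distribution
  below (no ties), normal approximation with mid-ranks, tie correction and
  continuity correction above. The threshold is configurable
  (`exactLimit`).
* **Degenerate genes.** A gene constant across the pooled sample carries
  no information: p = 1, flagged, never selected ahead of an informative
  gene; if every gene is degenerate, training fails with "no informative
  gene". A gene with zero within-class variance but different class means
  is perfectly separating: p = 0 with the statistic's sign from the mean
  difference.
* **Ties in the cut-point search.** With tied expression values across the
  class boundary, the candidate midpoint equals the shared value and the
  `<=` rule puts all tied samples on the left. Candidates at or above the
  maximum expression would induce a partition with an empty side and are
  excluded; this is what makes the candidate set empty (and triggers the
  mean fallback) exactly for constant genes, and it cannot change the
  entropy argmin otherwise, since a trivial partition's entropy equals the
  full class entropy.
* **Class identity.** The first class level — first appearance in the
  label file, or the first name in a CLS header — is $c_1$. Models bind
  class *names*, not positions, so predictions are label-stable.
* **DLDA variance floor**: zero pooled variances are floored at
  $10^{-8}\times$ the gene's mean absolute expression to avoid division by
  zero on degenerate fixtures.
* **Missing values are rejected** by the readers: imputation policy is out
  of scope and silent NA handling would corrupt the rank and entropy
  computations.
* **Serialisation**: models and reports are plain JSON with a schema
  version; numerics are written with 17 significant digits so a round trip
  reproduces the rule bit-exactly. SVM and random-forest fits contain
  opaque third-party state; persist those with `saveRDS`.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen as the smallest sizes at
which the quantities they measure are stable: cut-point oracle equivalence
on 1000 random instances of up to 12 samples; recovery and near-Bayes
accuracy at $\delta = 3$, $n_1 = n_2 = 20$, 1000 genes over 50 seeds; null
calibration on 50 label permutations of a 500-gene, 60-sample noise
dataset; contamination robustness over 50 seeds. `scripts/acceptance.R`
re-runs the same computations from scratch against the installed package.

## Known limitations

* Single cut point only: no multi-interval discretisation, and cut-point
  search is deliberately not part of gene selection (it would cost a
  factor of the candidate count per gene and risks selecting on overfit
  discretisations).
* No multiple-testing correction — selection is by raw p-value rank, and
  the 0.001 filter is used as-is, matching the method being implemented.
* Two classes only; multi-class extensions would change the entropy
  formula and the direction rule qualitatively.
* LOOCV accuracy on null data is noisy (a single dataset's LOOCV accuracy
  under the null has an SD of roughly 20 percentage points at $n = 60$);
  calibration statements are about means over many permutations.

## A worked example

```{r example}
sim <- simulateTwoClassData(n1 = 10, n2 = 10, nGenes = 100,
                            nInformative = 1, effectSizes = 5, seed = 7)
model <- trainSGC(sim$dataset, method = "t")
model

res <- loocv(sim$dataset, sgcTrainer("t"))
res
```
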