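---
title: "Predicting prokaryotic phenotypes from protein domain frequencies: models and methods"
author: "phenoDomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting prokaryotic phenotypes from protein domain frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoDomain)
```

## The problem

Many phenotypic traits of prokaryotes — whether an organism forms
endospores, stains Gram-positive, is motile, or requires oxygen — are
encoded collectively by many genes. phenoDomain predicts such traits
directly from an organism's *protein domain profile*: the vector of
occurrence counts of Pfam-A domain families detected across its genome
(d = 10797 families for Pfam-A release 23.0; 5665-cluster COG profiles
work identically). Because domains are short and detectable on partial
gene fragments, this representation is usable very early in a genome
project, before assembly or gene calling is complete.

The package consumes count matrices (families × organisms) and an
organism annotation table; domain detection itself (UFO, HMMER, RPS-BLAST)
is out of scope.

## Profile construction

Counts are first normalized to relative frequencies, so each organism's
profile $x \in [0,1]^d$ satisfies $\sum_{i=1}^d x_i = 1$. This removes
genome-size effects: multiplying an organism's counts by any constant
leaves its profile unchanged. Each dimension with non-zero standard
deviation is then scaled to unit *sample* standard deviation
(denominator $N-1$; the convention is documented and fixed because
either choice is defensible). Dimensions with zero variance are flagged
and left unscaled.

Two choices here were genuinely open:

* **Order of operations.** Frequencies first, then per-dimension
  scaling.
* **Scaler fitting population.** The scaler is fitted on training
  organisms only and applied unchanged to validation/test profiles.
  Fitting on the pooled data would leak distributional information
  across the evaluation split; the package consistently refits the
  scaler inside every split, fold and repetition.

Organisms with byte-identical count profiles (typically resequenced
strains) are reduced to a single representative — the first in input
order — before any training or evaluation, so a strain cluster cannot be
counted several times.

## The balanced RLSC learner

For $N$ training profiles $x_i$ with labels $y_i \in \{-1, +1\}$ the
package minimizes the balanced regularized least-squares error

$$E(w) = \sum_{i=1}^N b_i \, (y_i - w^{t} x_i)^2 + \lambda \lVert w \rVert^2,$$

where $b_i$ is the inverse size of the class example $i$ belongs to, so
each class contributes total weight 1 regardless of imbalance (phenotype
panels are often heavily skewed). There is no intercept; the decision
threshold is 0, and a score of exactly 0 classifies as negative (an
arbitrary, documented tie rule).

With the linear kernel $K = X^{t}X$ the minimizer has the dual form

$$\alpha = (K + \lambda B)^{-1} y, \qquad B = \mathrm{diag}(1/b_i),$$

i.e. $B$ carries the *class sizes* on its diagonal — the double
inversion is easy to get backwards, so the test suite pins it with a
stationarity check: the recovered primal discriminant $w = X\alpha$ must
satisfy $X B_w (y - X^{t} w) = \lambda w$ with $B_w = \mathrm{diag}(b)$,
and must agree with an independent closed-form primal solve and with a
generic BFGS minimizer of $E$.

The system is solved by Cholesky factorization without jitter:
$\lambda > 0$ and positive class sizes make $K + \lambda B$ positive
definite for any PSD kernel, so no regularization fudge is needed and
none is applied. Features are not centered.

Multi-class traits (e.g. oxygen requirement including facultative
organisms) replace $y$ by the 0/1 indicator matrix
$Y = [z_1, \ldots, z_M]$, yielding one weight column per class;
classification is by argmax over the class scores ("classification by
regression"). Balancing uses the same inverse-class-size rule.

Deployment needs only the primal discriminant: predicting a new organism
is one dot product in domain-profile space. Models serialize to a
versioned JSON file (17 significant digits, bit-exact round trip)
holding $\alpha$, $w$, $\lambda$, the class names, the scaler standard
deviations and the family-id order.

## Evaluation protocols and metrics

* **Random partitions:** 20 independent 70/30 train/validation splits.
* **Genus partitions:** whole genera are assigned to one side, so no
  genus used for training is ever used for assessment. This emulates
  predicting for organisms without close relatives in the reference
  collection. The split shuffles genera and fills the validation side
  greedily to ≈30% of organisms; 20 repetitions mirror the random
  scheme for comparability (the protocol's repetition count is not
  otherwise pinned down). Genus is the first whitespace token of the
  organism display name, case-normalized — applied literally, so
  "Candidatus" names yield the genus "Candidatus".
* **Repeated k-fold:** stratified 10-fold cross-validation repeated (by
  default 100 times); fold metrics are averaged within each repetition,
  and mean/std reported across repetitions. Stratification keeps both
  classes in every fold; plain random folds would occasionally produce
  single-class validation folds on skewed traits.

Metrics follow the protocol's definitions exactly:
$\mathrm{sens} = TP/(TP+FN)$ and $\mathrm{spec} = TP/(TP+FP)$. Note the
latter is the *positive-predictive* form — what most texts call
precision — so the reported harmonic mean
$2\cdot\mathrm{sens}\cdot\mathrm{spec}/(\mathrm{sens}+\mathrm{spec})$
is the standard F1 measure. `metricSet()` exposes a `precision` alias,
but the primary naming is kept so reported tables read consistently.
0/0 ratios are defined as 0. aucROC integrates the ROC curve
trapezoidally over distinct score thresholds with ties grouped (on
tie-free scores this equals the Mann–Whitney pair-counting statistic,
which the tests verify exactly); aucPRC is the area under the step-wise,
non-interpolated precision–recall curve. Report tables round to 3
decimals, half away from zero.

$\lambda$ is selected from the grid $\{10^m \mid m = -5, \ldots, 5\}$ by
the mean validation aucPRC over the random partitions, with ties going
to the smallest (most regularized solutions being preferred when
indistinguishable); one $\lambda$ is selected per phenotype and used for
all splits, rather than per split, so reported validation numbers
describe a single deployable model.

## Discriminative families and phylogenetic clustering

The primal discriminant is directly interpretable: `rankDomains()`
extracts the families with the 50 largest positive (indicative) and most
negative (counter-indicative) weights, with ties broken toward the lower
family index. Only strictly signed weights qualify, so either list may
be shorter than requested. Raw weights are reported, not normalized
ones.

For the top families, `phyloProfiles()` builds presence/absence patterns
across all organisms (count > 0), and `upgmaTree()` clusters them by
UPGMA with correlation distance $1 - r$. A constant profile has
undefined Pearson correlation; its distance is fixed at 1
(uninformative) rather than dropping the family. UPGMA is delegated to
`stats::hclust(method = "average")` behind the package's interface, and
the test suite verifies merge order and heights exactly against a naive
cubic-time implementation; tie-breaking between exactly equal distances
follows `hclust`. `colorClusters()` cuts the dendrogram at 70% of the
maximum merge height (the conventional dendrogram color threshold):
subtrees below the cut become clusters, singletons get a null color.
Raising the threshold only ever merges clusters, never splits them.
`exportNewick()` writes the tree with branch lengths derived from merge
heights (a leaf's branch equals its parent's height), and
`countPhylogroups()` reports in how many user-supplied phylogenetic
groups (e.g. NCBI phyla) each family occurs.

## The synthetic data generator

Real proteome collections with curated phenotype annotation are large
external datasets; the generator (`simulationSpec()` /
`generateDataset()`) emulates their statistical structure so every
pipeline stage is testable end-to-end:

* **Background composition.** Each genus draws a family composition
  from a symmetric Dirichlet($\alpha_{bg} = 0.1$) shared by its member
  organisms — a small concentration gives the sparse, skewed family
  usage typical of domain counts, and sharing it within a genus induces
  the correlation between close relatives that motivates the
  genus-partition protocol.
* **Genome sizes.** Per-organism total counts are log-uniform on
  2000–20000, spanning small parasites to large free-living genomes.
* **Causal families.** Each binary trait plants a set of indicative
  families, present (count ≥ 1, magnitude Poisson(3) truncated to ≥ 1)
  with probability $p^+ = 0.9$ in positives and $p^- = 0.05$ in
  negatives under the defaults (20 families, 300 organisms, no label
  noise — a strong-signal regime in which the ranking should recover
  the planted set). Counter-indicative families use the swapped
  probabilities. Causal families are excluded from the background
  composition so $p^\pm$ are exact presence probabilities.
* **Labels.** By default labels are drawn per organism, so the genus
  background is uninformative and performance must come from the
  planted families. With `genusLabels = TRUE` a whole genus shares one
  label: phenotype and phylogeny become confounded, random splits let
  the learner exploit genus backgrounds through shared-genus leakage,
  and genus-partitioned validation reveals the inflated estimate — the
  qualitative effect the genus-partition experiment exists to measure.
* **Label noise** flips annotation strings at a configurable rate while
  the ground truth keeps the pre-noise labels, which is how the
  annotation-audit workflow is exercised with known injected errors.

What the generator deliberately does *not* emulate: real Pfam
co-occurrence structure (domains of one operon or pathway co-occurring),
phylogenetic signal deeper than the genus level, unfinished-genome
truncation artifacts, and correlated annotation errors. Passing tests on
synthetic data therefore demonstrate the correctness of the machinery
and its qualitative behavior, not the accuracy attainable on real
proteome collections.

## Numerical choices and degenerate inputs

* All-zero organism profiles cannot be normalized and raise a
  degenerate-data error naming the organism.
* Zero-variance dimensions are left unscaled; a scaler applied to
  profiles of the wrong dimensionality raises a dimension error.
* Constant phylogenetic profiles get correlation distance 1.
* Dual solves never form an explicit inverse; the solve is a Cholesky
  factorization, valid for every $\lambda > 0$.
* The decision rule maps a score of exactly 0 to the negative class;
  multi-class argmax ties go to the lower class index.
* Degenerate $\lambda$ selection (constant scores on every split) warns
  and returns the smallest candidate.
* All randomness (splits, folds, simulations) flows from explicit seed
  arguments; every split function is a pure function of its inputs and
  seed, and the RNG state of the caller is never disturbed.

## Problem sizes used by the shipped checks

The package's own test and acceptance runs use deliberately compact
problem sizes, chosen to exercise every code path at desk scale: random
dual-vs-primal problems up to N = 100, d = 200; ten BFGS-oracle fixtures
at N = 15, d = 8; a hundred AUC oracle vectors up to n = 200; fifty
random UPGMA instances up to 12 leaves; the default 300 × 500 generator
spec over 20 seeds (with lambda selected over 5 random 70/30 partitions
inside that loop) for ranking recovery; and 10 simulated 120-organism
confounded datasets with 10 splits per scheme at fixed
$\lambda = 1$ for the genus-partition comparison. Scaling any of these
up is a matter of changing the corresponding arguments.

## Known limitations

* The learner is linear; traits whose genomic signature is purely
  combinatorial would need a nonlinear kernel, which is out of scope.
* "Specificity" follows the protocol's positive-predictive definition;
  users expecting the true-negative-rate convention should read the
  `precision` alias and documentation carefully.
* The genus-partition scheme needs at least two genera and leaves the
  exact validation fraction approximate (whole genera are indivisible).
* Multi-class traits are supported by the learner and decision rule,
  but the synthetic generator plants binary traits only; multi-class
  behavior is verified on constructed fixtures.
* `correlationDistMatrix()` is quadratic in the number of selected
  families — intended for the top-50 lists, not for all 10797 families.
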