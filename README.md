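# phenoDomain

Predicting phenotypic traits of prokaryotes — endospore formation, Gram
stain, motility, oxygen requirement and the like — directly from their
genome-wide **protein domain frequency profiles**.

Many microbial phenotypes are polygenic, and for a growing share of
sequenced organisms (single-cell assemblies, metagenome bins, early-stage
genome projects) the genome arrives long before any experimental
characterization. phenoDomain is for bioinformaticians who want to infer
such traits from sequence-derived features alone: it consumes a matrix of
Pfam-A domain occurrence counts per organism (10797 families for Pfam-A
v23.0; COG cluster counts work the same way) plus a phenotype annotation
table, and learns a discriminative linear model per trait. Because
domains are detectable on short coding fragments, predictions are
possible even before assembly.

## The model

Profiles are normalized to relative frequencies
(x ∈ [0,1]^d, Σᵢ xᵢ = 1) and each non-degenerate dimension is scaled to
unit sample standard deviation. Training minimizes the **balanced
regularized least-squares (RLSC)** error over N labeled organisms,

&nbsp;&nbsp;&nbsp;&nbsp;E(w) = Σᵢ bᵢ (yᵢ − wᵗxᵢ)² + λ‖w‖²,&nbsp;&nbsp; yᵢ ∈ {−1, +1},

with bᵢ the inverse size of example i's class, so imbalanced phenotype
panels cannot swamp the minority class. With the linear kernel
K = XᵗX the minimizer is obtained in dual form,

&nbsp;&nbsp;&nbsp;&nbsp;α = (K + λB)⁻¹ y,&nbsp;&nbsp; B = diag(1/bᵢ),

solved by Cholesky factorization, and the primal discriminant
w = Xα turns prediction for a new organism into a single dot product in
domain-profile space. Multi-class traits replace y by a 0/1 indicator
matrix (classification by regression, argmax decision rule). λ is chosen
from the grid 10⁻⁵…10⁵ by mean validation aucPRC over twenty random
70/30 partitions; a **genus-partitioned** protocol (whole genera held
out) measures how much accuracy depends on close relatives being present
in training. The sorted entries of w rank domain families by how
indicative / counter-indicative they are of the trait, and UPGMA
clustering of their presence/absence ("phylogenetic") profiles with
correlation distance groups them into candidate functional modules.

See `vignettes/phenotype-prediction-methods.Rmd` for the full account of
the methods, parameter choices and limitations.

## Worked example

On a synthetic dataset with known planted signal (300 organisms, 500
families, 20 causal families for the trait):

```r
library(phenoDomain)

ds <- generateDataset(simulationSpec(), seed = 1)
model <- trainPhenotypeModel(ds$counts, ds$annotation, "Endospores",
                             reps = 5, seed = 1)
model
#> RLSCModel (binary) for 'Endospores': 300 training examples, d = 500, lambda = 1
```

`lambda = 1` was selected because it maximizes the mean validation
aucPRC across the selection partitions (`attr(model, "selection")` shows
the per-λ table; here 0.936 at λ = 1 against 0.829 at λ = 10⁻⁵). Ranking
the primal discriminant recovers the planted families:

```r
rk <- rankDomains(primalDiscriminant(model), n = 50)
head(rk@indicative, 3)
#>   rank family_id     weight
#> 1    1   SF00260 0.08052871
#> 2    2   SF00472 0.07808407
#> 3    3   SF00127 0.07782754

recoveryReport(rk, ds$truth)$fraction
#> [1] 0.95
```

i.e. 19 of the 20 planted causal families appear among the top-50
indicative weights. Prediction returns a score (signed distance from
the decision boundary, positive = trait present) and the mapped
annotation string per organism:

```r
head(predictPhenotype(model, ds$counts), 3)
#>   organism_id      score label predicted
#> 1     org0001  0.5003855     1       yes
#> 2     org0002 -0.3167941    -1        no
#> 3     org0003 -0.7810629    -1        no
```

`runValidationExperiment()` contrasts random and genus-partitioned
validation, `upgmaTree()` / `exportNewick()` cluster the top families'
phylogenetic profiles, and `discrepancyReport()` lists organisms whose
annotation contradicts the model — candidates for annotation errors. The
same workflows are scriptable through the command-line wrapper
(`inst/scripts/phenodomain.R` with subcommands `simulate`, `train`,
`predict`, `evaluate`, `rank-domains`, `cluster`, `audit`).

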