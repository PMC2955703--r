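#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' DomainCountSet: organism protein-domain occurrence counts
#'
#' Container for a domain (or COG) count matrix: rows are Pfam-A families
#' (or COG clusters), columns are organisms, entries are non-negative
#' integer occurrence counts as produced by a genome-wide domain detection.
#' Extends [SummarizedExperiment::SummarizedExperiment]; organism metadata
#' (display name, sequencing status, phenotype annotation strings) lives in
#' `colData`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("DomainCountSet", contains = "SummarizedExperiment")

setValidity("DomainCountSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("counts" %in% a)) {
    return("assay 'counts' is required")
  }
  m <- SummarizedExperiment::assay(object, "counts")
  if (!is.numeric(m)) {
    return("counts must be numeric")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    return("counts must be finite and non-missing")
  }
  if (any(m < 0)) {
    return("counts must be non-negative")
  }
  if (any(m %% 1 != 0)) {
    return("counts must be whole numbers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    return("family ids (rownames) must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    return("organism ids (colnames) must be present and unique")
  }
  TRUE
})

#' Construct a DomainCountSet
#'
#' @param counts numeric matrix of non-negative integer counts,
#'   families x organisms (the layout of the count-matrix CSV).
#' @param familyIds,organismIds optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @param annotation optional organism annotation `data.frame` with an
#'   `organism_id` column; matched rows become `colData`.
#' @return a [DomainCountSet-class] object.
#' @export
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 2L), nrow = 2,
#'             dimnames = list(c("PF00001", "PF00002"), c("orgA", "orgB")))
#' DomainCountSet(m)
DomainCountSet <- function(counts, familyIds = rownames(counts),
                           organismIds = colnames(counts),
                           annotation = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  rownames(counts) <- familyIds
  colnames(counts) <- organismIds
  cd <- S4Vectors::DataFrame(row.names = organismIds)
  if (!is.null(annotation)) {
    pdAssert("organism_id" %in% colnames(annotation), "pdFormatError",
             "annotation table must have an 'organism_id' column")
    idx <- match(organismIds, annotation$organism_id)
    cd <- S4Vectors::DataFrame(annotation[idx, , drop = FALSE],
                               row.names = organismIds, check.names = FALSE)
  }
  new("DomainCountSet",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd))
}

#' ProfileMatrix: normalized domain frequency profiles
#'
#' Rows are organisms, columns are domain families. Before scaling each row
#' is a relative-frequency vector (non-negative, summing to 1); after
#' per-dimension unit-std scaling, entries may exceed 1 but remain
#' non-negative.
#'
#' @slot values numeric matrix, organisms x families.
#' @slot scaled logical; whether per-dimension std scaling was applied.
#' @slot scaler the [ScalingModel-class] applied, or `NULL`.
#' @export
setClass("ProfileMatrix",
         representation(values = "matrix", scaled = "logical",
                        scaler = "ANY"))

setValidity("ProfileMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("profile values must be non-negative")
  if (!isTRUE(object@scaled)) {
    rs <- rowSums(v)
    if (nrow(v) > 0 && any(abs(rs - 1) > 1e-9)) {
      return("unscaled profile rows must sum to 1 (within 1e-9)")
    }
    if (any(v > 1 + 1e-12)) {
      return("unscaled profile entries must lie in [0, 1]")
    }
  }
  TRUE
})

#' ScalingModel: per-dimension standard deviations
#'
#' Fitted sample standard deviations (denominator N-1) of each profile
#' dimension on a training population. Dimensions with std 0 are flagged
#' and left unscaled when applied.
#'
#' @slot sds named numeric vector of per-dimension standard deviations.
#' @slot nFit number of organisms the scaler was fitted on.
#' @export
setClass("ScalingModel",
         representation(sds = "numeric", nFit = "integer"))

setValidity("ScalingModel", function(object) {
  if (anyNA(object@sds) || any(object@sds < 0)) {
    return("standard deviations must be non-negative and non-missing")
  }
  TRUE
})

#' PhenotypeLabels: per-organism class labels for one phenotype
#'
#' For binary traits labels are +1 / -1 / `NA` (missing); for multi-class
#' traits they are class indices 1..M / `NA`. Organisms with missing labels
#' are excluded from training and evaluation.
#'
#' @slot phenotype phenotype name (annotation column).
#' @slot labels named integer vector (names = organism ids).
#' @slot classNames for binary, `c(negative, positive)` annotation strings;
#'   for multi-class, the M class strings in index order.
#' @slot scheme `"binary"` or `"multiclass"`.
#' @export
setClass("PhenotypeLabels",
         representation(phenotype = "character", labels = "integer",
                        classNames = "character", scheme = "character"))

setValidity("PhenotypeLabels", function(object) {
  if (!object@scheme %in% c("binary", "multiclass")) {
    return("scheme must be 'binary' or 'multiclass'")
  }
  lab <- object@labels
  if (length(lab) && is.null(names(lab))) {
    return("labels must be named by organism id")
  }
  ok <- lab[!is.na(lab)]
  if (object@scheme == "binary") {
    if (!all(ok %in% c(-1L, 1L))) return("binary labels must be +1/-1/NA")
  } else {
    m <- length(object@classNames)
    if (length(ok) && (any(ok < 1L) || any(ok > m))) {
      return("multiclass labels must index classNames")
    }
  }
  TRUE
})

#' BalanceWeights: per-example class-balancing factors
#'
#' `b[i]` is the inverse size of the class example i belongs to, so each
#' class contributes total weight 1; `Bdiag[i] = 1/b[i]` (the class size)
#' is the diagonal of the matrix B added to the kernel in the dual solve.
#'
#' @slot b numeric vector of balancing factors.
#' @slot Bdiag numeric vector, elementwise inverse of `b`.
#' @export
setClass("BalanceWeights",
         representation(b = "numeric", Bdiag = "numeric"))

setValidity("BalanceWeights", function(object) {
  if (any(object@b <= 0) || any(object@Bdiag <= 0)) {
    return("balance weights must be positive")
  }
  if (max(abs(object@b * object@Bdiag - 1)) > 1e-12) {
    return("Bdiag must be the elementwise inverse of b")
  }
  TRUE
})

#' RLSCModel: a trained balanced regularized least-squares classifier
#'
#' Stores the dual weights alpha solving `(K + lambda B) alpha = y` on the
#' training kernel, the training profiles (for dual prediction), and the
#' recovered primal discriminant `w = X^t alpha` in domain-profile space
#' (for fast deployment as a single dot product per organism).
#'
#' @slot alpha N x M matrix of dual weights (M = 1 for binary problems).
#' @slot lambda regularization parameter (> 0).
#' @slot X training profile matrix, organisms x families (may have zero
#'   rows for a deserialized model, in which case prediction uses the
#'   primal discriminant).
#' @slot discriminant d x M primal weight matrix.
#' @slot y training label encoding (numeric N x M as used in the solve).
#' @slot classNames,scheme,phenotype label metadata (see
#'   [PhenotypeLabels-class]).
#' @slot scaler the [ScalingModel-class] the profiles were scaled with, or
#'   `NULL`.
#' @slot familyIds family-id order of the discriminant dimensions.
#' @export
setClass("RLSCModel",
         representation(alpha = "matrix", lambda = "numeric", X = "matrix",
                        discriminant = "matrix", y = "matrix",
                        classNames = "character", scheme = "character",
                        phenotype = "character", scaler = "ANY",
                        familyIds = "character"))

setValidity("RLSCModel", function(object) {
  if (length(object@lambda) != 1L || object@lambda <= 0) {
    return("lambda must be a single positive number")
  }
  if (ncol(object@discriminant) != ncol(object@alpha)) {
    return("discriminant and alpha must have one column per class")
  }
  if (nrow(object@discriminant) != length(object@familyIds)) {
    return("discriminant rows must match familyIds")
  }
  TRUE
})

#' Discriminant: primal weight vector(s) in domain-profile space
#'
#' @slot weights d x M numeric matrix (rownames = family ids); one column
#'   per class, a single column for binary problems.
#' @slot classNames class names for the columns.
#' @export
setClass("Discriminant",
         representation(weights = "matrix", classNames = "character"))

#' RankedDomains: discriminative domain families
#'
#' Two ranked lists extracted from a primal discriminant: families with the
#' n largest positive (indicative) and most negative (counter-indicative)
#' weights.
#'
#' @slot indicative,counterIndicative `data.frame`s with columns `rank`,
#'   `family_id`, `weight` (and `group_count` when a phylogroup map was
#'   supplied).
#' @slot n requested list length.
#' @export
setClass("RankedDomains",
         representation(indicative = "data.frame",
                        counterIndicative = "data.frame", n = "integer"))

#' LinkageTree: UPGMA dendrogram over phylogenetic profiles
#'
#' Wraps the merge structure of an average-linkage (UPGMA) clustering:
#' `merges[k, ]` lists the two children of internal node k (negative =
#' leaf index, positive = earlier merge), `heights[k]` its merge height.
#' UPGMA guarantees heights are non-decreasing along any root path.
#'
#' @slot merges (n-1) x 2 integer matrix in [stats::hclust] convention.
#' @slot heights merge heights.
#' @slot labels leaf labels (family ids).
#' @slot hc the underlying `hclust` object.
#' @export
setClass("LinkageTree",
         representation(merges = "matrix", heights = "numeric",
                        labels = "character", hc = "ANY"))

setValidity("LinkageTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merges) != n - 1L) {
    return("a tree over n leaves must have n-1 merges")
  }
  if (any(diff(object@heights) < -1e-12)) {
    return("UPGMA merge heights must be non-decreasing")
  }
  TRUE
})

#' SimulationSpec: parameters of the synthetic dataset generator
#'
#' Defaults describe a strong-signal study: 300 organisms in 30 genera over
#' 500 families, one binary trait with 20 planted indicative families
#' present with probability 0.9 in positives and 0.05 in negatives, no
#' label noise. See the methods vignette for the rationale of each value.
#'
#' @slot nOrganisms,nFamilies,nGenera integers.
#' @slot traits list of per-trait specs (see [simulationSpec()]).
#' @slot alphaBg symmetric Dirichlet concentration of the background
#'   family propensities (shared within a genus).
#' @slot genomeSizeRange log-uniform bounds on per-organism total counts.
#' @slot labelNoise probability an annotation string is flipped.
#' @slot genusLabels logical; assign trait labels at genus level.
#' @export
setClass("SimulationSpec",
         representation(nOrganisms = "integer", nFamilies = "integer",
                        nGenera = "integer", traits = "list",
                        alphaBg = "numeric", genomeSizeRange = "numeric",
                        labelNoise = "numeric", genusLabels = "logical"))

setValidity("SimulationSpec", function(object) {
  if (object@nOrganisms < 2L || object@nFamilies < 2L ||
      object@nGenera < 1L) {
    return("need at least 2 organisms, 2 families and 1 genus")
  }
  if (object@labelNoise < 0 || object@labelNoise > 1) {
    return("labelNoise must be in [0, 1]")
  }
  if (length(object@genomeSizeRange) != 2L ||
      any(object@genomeSizeRange < 1) ||
      diff(object@genomeSizeRange) < 0) {
    return("genomeSizeRange must be increasing and >= 1")
  }
  tot <- 0L
  for (tr in object@traits) {
    if (tr$pPos <= tr$pNeg) {
      return("each trait needs pPos > pNeg (indicative planting)")
    }
    if (tr$pPos > 1 || tr$pNeg < 0) return("probabilities must be in [0,1]")
    if (tr$positiveFraction <= 0 || tr$positiveFraction >= 1) {
      return("positiveFraction must be in (0, 1)")
    }
    tot <- tot + tr$nCausal + tr$nCounterCausal
  }
  if (tot > object@nFamilies) {
    return("total causal families exceed nFamilies")
  }
  TRUE
})

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot causalFamilies named list (one entry per trait) of
#'   `list(indicative =, counterIndicative =)` family-id vectors.
#' @slot trueLabels named list of pre-noise +1/-1 label vectors.
#' @export
setClass("GroundTruth",
         representation(causalFamilies = "list", trueLabels = "list"))
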