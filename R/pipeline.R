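## End-to-end workflows: train a phenotype model from a count matrix and
## annotation table, predict phenotypes for new organisms, audit
## annotation against predictions.

#' Train a phenotype model from counts and annotation
#'
#' Full training pipeline: deduplicate identical count profiles, parse the
#' phenotype labels, normalize to relative frequencies, select lambda by
#' mean validation aucPRC over random 70/30 partitions (unless fixed), fit
#' the std scaler on the training organisms, and train the balanced RLSC
#' model on all labeled organisms.
#'
#' @param counts a [DomainCountSet-class].
#' @param annotation annotation `data.frame` ([readAnnotation()]).
#' @param phenotype annotation column name.
#' @param lambda fixed regularization parameter; NULL selects from
#'   [lambdaGrid()].
#' @param positive,negative annotation strings (see [parseAnnotation()]).
#' @param reps partitions used for lambda selection.
#' @param seed RNG seed for the selection partitions.
#' @return an [RLSCModel-class]; the per-lambda selection table (if any)
#'   is attached as `attr(, "selection")`.
#' @export
trainPhenotypeModel <- function(counts, annotation, phenotype,
                                lambda = NULL, positive = NULL,
                                negative = NULL, reps = 20, seed = 1) {
  dat <- .phenotypeData(counts, annotation, phenotype,
                        positive = positive, negative = negative)
  pdAssert(!is.null(dat), "pdDegenerateError",
           "no labeled organisms for phenotype '", phenotype, "'")
  pdAssert(length(unique(dat$lab)) >= 2L, "pdDegenerateError",
           "phenotype '", phenotype, "' has a single class")
  prof <- new("ProfileMatrix", values = dat$values, scaled = FALSE,
              scaler = NULL)
  selTab <- NULL
  if (is.null(lambda)) {
    sel <- selectLambda(prof, dat$lab, reps = reps, seed = seed)
    lambda <- sel$lambda
    selTab <- sel$table
  }
  sc <- fitScaler(prof)
  model <- rlscTrain(applyScaler(prof, sc), dat$labels, lambda)
  attr(model, "selection") <- selTab
  model
}

#' Predict phenotypes for a count matrix
#'
#' Normalizes the counts, applies the model's training scaler, computes
#' prediction scores and the decision-rule labels.
#'
#' @param model an [RLSCModel-class].
#' @param counts a [DomainCountSet-class] over the same family universe.
#' @return `data.frame` with `organism_id`, `score`, `label` (+1/-1 or
#'   class index) and `predicted` (the annotation string).
#' @export
predictPhenotype <- function(model, counts) {
  pdAssert(length(familyIds(counts)) == length(model@familyIds) &&
             all(familyIds(counts) == model@familyIds),
           "pdDimensionError",
           "count matrix families do not match the model's family ids")
  prof <- normalizeToFrequencies(counts)
  if (is(model@scaler, "ScalingModel")) {
    prof <- applyScaler(prof, model@scaler)
  }
  scores <- predictScores(model, prof)
  if (model@scheme == "binary") {
    lab <- classifyScores(scores)
    data.frame(organism_id = organismIds(counts),
               score = as.numeric(scores), label = lab,
               predicted = ifelse(lab == 1L, model@classNames[2],
                                  model@classNames[1]),
               stringsAsFactors = FALSE)
  } else {
    lab <- classifyScores(scores)
    data.frame(organism_id = organismIds(counts),
               score = scores[cbind(seq_along(lab), lab)], label = lab,
               predicted = model@classNames[lab],
               stringsAsFactors = FALSE)
  }
}

#' Annotation-discrepancy report
#'
#' Compares predictions with the existing phenotype annotation and lists
#' every disagreement, strongest contradictions (largest absolute score)
#' first — candidates for annotation errors worth literature follow-up.
#' Organisms without annotation are skipped.
#'
#' @param predictions `data.frame` from [predictPhenotype()].
#' @param labels a [PhenotypeLabels-class] for the same organisms.
#' @return `data.frame` with columns `organism_id`, `phenotype`,
#'   `annotated`, `predicted`, `score`.
#' @export
discrepancyReport <- function(predictions, labels) {
  lab <- labels@labels[predictions$organism_id]
  keep <- !is.na(lab) & lab != predictions$label
  annStr <- ifelse(lab == 1L, labels@classNames[2], labels@classNames[1])
  out <- data.frame(organism_id = predictions$organism_id[keep],
                    phenotype = rep(labels@phenotype, sum(keep)),
                    annotated = annStr[keep],
                    predicted = predictions$predicted[keep],
                    score = predictions$score[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$score)), , drop = FALSE]
}
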