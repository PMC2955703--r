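## Experiment drivers: lambda selection by mean validation aucPRC,
## repeated stratified k-fold evaluation, and the random-vs-genus
## validation experiment.

## Train on the split's training side (scaler fitted on training organisms
## only) and score the validation side.
.evalSplit <- function(values, lab, split, lambda) {
  trV <- values[split$train, , drop = FALSE]
  vaV <- values[split$validation, , drop = FALSE]
  trP <- new("ProfileMatrix", values = trV, scaled = FALSE, scaler = NULL)
  sc <- fitScaler(trP)
  model <- rlscTrain(applyScaler(trP, sc), lab[split$train], lambda)
  vaP <- applyScaler(new("ProfileMatrix", values = vaV, scaled = FALSE,
                         scaler = NULL), sc)
  list(scores = predictScores(model, vaP), truth = lab[split$validation])
}

#' Select the regularization parameter by mean validation aucPRC
#'
#' For every lambda on the grid, trains on each partition's training side
#' and computes the area under the precision-recall curve on its
#' validation side; returns the lambda with the highest mean aucPRC (ties
#' go to the smallest lambda). When every split yields constant scores the
#' selection is degenerate: a warning is raised and the smallest lambda
#' returned.
#'
#' @param profiles unscaled [ProfileMatrix-class] of the labeled organisms.
#' @param labels label vector (+1/-1) aligned with `profiles` rows.
#' @param grid candidate lambdas (default [lambdaGrid()]).
#' @param splits list of partitions (default: `reps` random 70/30 splits).
#' @param reps,seed used when `splits` is NULL.
#' @return `list(lambda =, table =)` with the per-lambda mean aucPRC table.
#' @export
selectLambda <- function(profiles, labels, grid = lambdaGrid(),
                         splits = NULL, reps = 20, seed = 1) {
  pdAssert(length(grid) >= 1L, "pdValueError", "empty lambda grid")
  values <- profileValues(profiles)
  lab <- if (is(labels, "PhenotypeLabels")) labels@labels else labels
  pdAssert(length(lab) == nrow(values), "pdDimensionError",
           "labels and profiles disagree in length")
  if (is.null(splits)) {
    splits <- makeRandomPartitions(nrow(values), reps = reps, seed = seed)
  }
  grid <- sort(grid)
  anySignal <- FALSE
  means <- vapply(grid, function(lam) {
    aucs <- vapply(splits, function(sp) {
      ev <- .evalSplit(values, lab, sp, lam)
      if (length(unique(ev$scores)) > 1L) anySignal <<- TRUE
      curveMetrics(ev$scores, ev$truth)$auc_prc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(lambda = grid, mean_auc_prc = means)
  if (!anySignal || all(!is.finite(means))) {
    warning("degenerate selection: constant scores on every split; ",
            "returning the smallest lambda")
    return(list(lambda = grid[1], table = tab))
  }
  list(lambda = grid[which.max(means)], table = tab)
}

#' Repeated stratified k-fold cross-validation
#'
#' Repeats a stratified k-fold cross-validation `reps` times with fresh
#' random fold assignments. Within each repetition, metrics (aucROC,
#' aucPRC, the product of sensitivity and specificity, the harmonic mean)
#' are computed per fold and averaged over the k folds; the mean/std over
#' repetitions is attached as a summary.
#'
#' @param profiles unscaled [ProfileMatrix-class] of the labeled organisms.
#' @param labels +1/-1 label vector aligned with `profiles` rows.
#' @param k folds (default 10).
#' @param reps repetitions (default 100).
#' @param lambda regularization parameter.
#' @param seed RNG seed.
#' @return `data.frame` with one row per repetition; the mean/std summary
#'   is attached as `attr(, "summary")`.
#' @export
repeatedKFoldEval <- function(profiles, labels, k = 10, reps = 100,
                              lambda = 1, seed = 1) {
  values <- profileValues(profiles)
  lab <- if (is(labels, "PhenotypeLabels")) labels@labels else labels
  pdAssert(length(lab) == nrow(values), "pdDimensionError",
           "labels and profiles disagree in length")
  res <- lapply(seq_len(reps), function(r) {
    folds <- makeStratifiedFolds(lab, k = k, seed = seed + r - 1L)
    perFold <- vapply(sort(unique(folds)), function(f) {
      sp <- list(train = which(folds != f), validation = which(folds == f))
      ev <- .evalSplit(values, lab, sp, lambda)
      cm <- curveMetrics(ev$scores, ev$truth)
      ms <- metricSet(confusionCounts(classifyScores(ev$scores), ev$truth))
      c(cm$auc_roc, cm$auc_prc, ms$sens_times_spec, ms$harmonic_mean)
    }, numeric(4))
    avg <- rowMeans(perFold, na.rm = TRUE)
    data.frame(rep = r, auc_roc = avg[1], auc_prc = avg[2],
               sens_times_spec = avg[3], harmonic_mean = avg[4])
  })
  out <- do.call(rbind, res)
  num <- out[, -1, drop = FALSE]
  attr(out, "summary") <- data.frame(
    metric = colnames(num),
    mean = colMeans(num),
    std = apply(num, 2L, stats::sd),
    row.names = NULL)
  out
}

## Assemble the labeled, deduplicated frequency matrix + labels + genera
## for one phenotype.
.phenotypeData <- function(counts, annotation, phenotype, positive = NULL,
                           negative = NULL) {
  dd <- deduplicateProfiles(counts)
  labels <- parseAnnotation(annotation, phenotype, scheme = "binary",
                            positive = positive, negative = negative)
  lab <- labels@labels
  ids <- intersect(organismIds(dd$counts), names(lab)[!is.na(lab)])
  if (length(ids) == 0L) {
    return(NULL)
  }
  prof <- normalizeToFrequencies(dd$counts)
  values <- profileValues(prof)[ids, , drop = FALSE]
  nm <- annotation$organism_name[match(ids, annotation$organism_id)]
  list(values = values, lab = lab[ids], genera = extractGenus(nm),
       labels = labels)
}

.meanHarmonic <- function(values, lab, splits, lambda) {
  hs <- vapply(splits, function(sp) {
    ev <- .evalSplit(values, lab, sp, lambda)
    ms <- metricSet(confusionCounts(classifyScores(ev$scores), ev$truth))
    ms$harmonic_mean
  }, numeric(1))
  mean(hs)
}

#' Validation experiment: random vs. genus-partitioned splits
#'
#' For each phenotype, reports the mean validation harmonic mean over
#' random 70/30 partitions, the same over genus-partitioned splits (whole
#' genera held out), and their difference — the performance decline caused
#' by removing close relatives from the validation side. An `average` row
#' over phenotypes is appended. One lambda is used for all splits of a
#' phenotype (selected on the random partitions when `lambda` is NULL).
#'
#' @param counts a [DomainCountSet-class].
#' @param annotation annotation `data.frame`.
#' @param phenotypes phenotype column names.
#' @param lambda fixed regularization parameter, or NULL to select per
#'   phenotype via [selectLambda()].
#' @param reps splits per scheme (default 20).
#' @param seed RNG seed.
#' @return `data.frame` with columns `phenotype`, `harmonic_random`,
#'   `harmonic_genus`, `difference`.
#' @export
runValidationExperiment <- function(counts, annotation, phenotypes,
                                    lambda = NULL, reps = 20, seed = 1) {
  rows <- list()
  for (ph in phenotypes) {
    dat <- .phenotypeData(counts, annotation, ph)
    if (is.null(dat) || length(unique(dat$lab)) < 2L) {
      warning("phenotype '", ph, "' has fewer than two classes; skipped")
      next
    }
    lam <- lambda
    if (is.null(lam)) {
      prof <- new("ProfileMatrix", values = dat$values, scaled = FALSE,
                  scaler = NULL)
      lam <- selectLambda(prof, dat$lab, reps = reps, seed = seed)$lambda
    }
    rnd <- makeRandomPartitions(length(dat$lab), reps = reps, seed = seed)
    gen <- makeGenusPartitions(dat$genera, reps = reps, seed = seed)
    hr <- .meanHarmonic(dat$values, dat$lab, rnd, lam)
    hg <- .meanHarmonic(dat$values, dat$lab, gen, lam)
    rows[[ph]] <- data.frame(phenotype = ph, harmonic_random = hr,
                             harmonic_genus = hg, difference = hg - hr)
  }
  pdAssert(length(rows) > 0L, "pdValueError",
           "no phenotype could be evaluated")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  avg <- data.frame(phenotype = "average",
                    harmonic_random = mean(out$harmonic_random),
                    harmonic_genus = mean(out$harmonic_genus),
                    difference = mean(out$difference))
  rbind(out, avg)
}
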