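test_that("random partitions are reproducible 70/30 covers", {
  sp <- makeRandomPartitions(10, reps = 20, seed = 4)
  expect_length(sp, 20)
  for (s in sp) {
    expect_length(s$train, 7)
    expect_length(s$validation, 3)
    expect_identical(sort(c(s$train, s$validation)), 1:10)
    expect_length(intersect(s$train, s$validation), 0)
  }
  expect_identical(sp, makeRandomPartitions(10, reps = 20, seed = 4))
  expect_false(identical(sp, makeRandomPartitions(10, reps = 20, seed = 5)))
  expect_error(makeRandomPartitions(3), class = "pdValueError")
})

test_that("genus partitions never split a genus", {
  genera <- c("Bacillus", "Bacillus", "Escherichia", "Clostridium")
  sp <- makeGenusPartitions(genera, reps = 50, seed = 2)
  for (s in sp) {
    expect_length(intersect(genera[s$train], genera[s$validation]), 0)
    expect_gt(length(s$train), 0)
    expect_gt(length(s$validation), 0)
  }
  expect_identical(sp, makeGenusPartitions(genera, reps = 50, seed = 2))

  # 10 equal genera at fraction 0.3 -> greedy fill puts 3 in validation
  g10 <- rep(sprintf("G%02d", 1:10), each = 4)
  for (s in makeGenusPartitions(g10, reps = 10, seed = 9)) {
    expect_length(unique(g10[s$validation]), 3)
  }
  expect_error(makeGenusPartitions(rep("Bacillus", 5)),
               class = "pdValueError")
})

test_that("confusion counts follow the +1-positive convention", {
  cc <- confusionCounts(c(1L, 1L, -1L, -1L), c(1L, -1L, 1L, -1L))
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  perf <- confusionCounts(c(1L, -1L), c(1L, -1L))
  expect_equal(perf$FP + perf$FN, 0L)
  allPos <- confusionCounts(c(1L, 1L), c(1L, -1L))
  expect_equal(allPos, list(TP = 1L, FP = 1L, TN = 0L, FN = 0L))
  expect_error(confusionCounts(1L, c(1L, -1L)), class = "pdValueError")
})

test_that("point metrics reproduce the published worked examples", {
  # harmonic means recomputed from sensitivity/precision pairs
  expect_equal(roundHalfUp(harmonicMean(0.913, 0.875)), 0.894)
  expect_equal(roundHalfUp(harmonicMean(0.993, 0.907)), 0.948)
  expect_equal(roundHalfUp(harmonicMean(0.992, 0.963)), 0.977)
  # column averages of the validation experiment layout
  expect_equal(roundHalfUp(mean(c(0.946, 0.966, 0.932, 0.973))), 0.954)
  expect_equal(roundHalfUp(mean(c(0.821, 0.905, 0.870, 0.949))), 0.886)
  expect_equal(roundHalfUp(mean(c(-0.125, -0.061, -0.062, -0.024))), -0.068)

  ms <- metricSet(list(TP = 8L, FP = 2L, TN = 5L, FN = 1L))
  expect_equal(ms$sensitivity, 8 / 9)
  expect_equal(ms$specificity, 8 / 10)  # TP/(TP+FP): the precision form
  expect_identical(ms$precision, ms$specificity)
  expect_equal(ms$harmonic_mean,
               2 * ms$sensitivity * ms$specificity /
                 (ms$sensitivity + ms$specificity))
  expect_equal(ms$classification_error, 3 / 16)
  # 0/0 ratios are 0
  z <- metricSet(list(TP = 0L, FP = 0L, TN = 3L, FN = 0L))
  expect_equal(z$sensitivity, 0)
  expect_equal(z$harmonic_mean, 0)
})

test_that("curve metrics match hand-enumerated and pair-counting oracles", {
  cm <- curveMetrics(c(0.9, 0.8, 0.4, 0.2), c(1L, -1L, 1L, -1L))
  # ROC points (0,0),(0,.5),(.5,.5),(.5,1),(1,1) -> area 0.75
  expect_equal(cm$auc_roc, 0.75)
  # perfect separation
  sep <- curveMetrics(c(3, 2, -1, -2), c(1L, 1L, -1L, -1L))
  expect_equal(sep$auc_roc, 1)
  expect_equal(sep$auc_prc, 1)
  # Mann-Whitney equivalence on tie-free scores
  set.seed(17)
  for (r in 1:25) {
    n <- sample(10:200, 1)
    truth <- sample(c(-1L, 1L), n, replace = TRUE)
    if (length(unique(truth)) == 1L) truth[1] <- -truth[1]
    scores <- rnorm(n)
    expect_equal(curveMetrics(scores, truth)$auc_roc,
                 pairCountAUC(scores, truth), tolerance = 1e-12)
  }
  # metric bounds
  set.seed(18)
  for (r in 1:10) {
    truth <- sample(c(-1L, 1L), 30, replace = TRUE)
    if (length(unique(truth)) == 1L) truth[1] <- -truth[1]
    cm <- curveMetrics(rnorm(30), truth)
    expect_true(cm$auc_roc >= 0 && cm$auc_roc <= 1)
    expect_true(cm$auc_prc >= 0 && cm$auc_prc <= 1)
  }
  # single-class scores are undefined
  expect_true(is.na(curveMetrics(c(1, 2), c(1L, 1L))$auc_roc))
})

test_that("the harmonic mean is bounded by the arithmetic mean", {
  set.seed(19)
  s1 <- runif(50)
  s2 <- runif(50)
  expect_true(all(harmonicMean(s1, s2) <= (s1 + s2) / 2 + 1e-12))
  expect_true(all(harmonicMean(s1, s2) >= 0))
})

test_that("lambda selection maximizes mean validation aucPRC", {
  expect_equal(length(lambdaGrid()), 11L)
  expect_equal(lambdaGrid(), 10^(-5:5))

  set.seed(23)
  ds <- generateDataset(simulationSpec(nOrganisms = 80, nFamilies = 60,
                                       nGenera = 8,
                                       traits = list(list(
                                         name = "Endospores",
                                         positiveFraction = 0.5,
                                         nCausal = 8, nCounterCausal = 0,
                                         pPos = 1, pNeg = 0))), seed = 23)
  prof <- normalizeToFrequencies(ds$counts)
  lab <- parseAnnotation(ds$annotation, "Endospores")@labels
  grid <- c(0.01, 1, 100)
  splits <- makeRandomPartitions(80, reps = 5, seed = 23)
  sel <- selectLambda(prof, lab, grid = grid, splits = splits)
  # exhaustive oracle: the selected lambda attains the max of the table
  expect_equal(max(sel$table$mean_auc_prc),
               sel$table$mean_auc_prc[sel$table$lambda == sel$lambda])
  # single candidate returns itself
  one <- selectLambda(prof, lab, grid = 1, splits = splits)
  expect_equal(one$lambda, 1)
  # ties go to the smallest lambda (separable data saturates aucPRC = 1)
  if (sum(sel$table$mean_auc_prc == max(sel$table$mean_auc_prc)) > 1) {
    expect_equal(sel$lambda,
                 min(sel$table$lambda[sel$table$mean_auc_prc ==
                                        max(sel$table$mean_auc_prc)]))
  }
})

test_that("repeated stratified k-fold evaluation is deterministic and sane", {
  set.seed(29)
  ds <- generateDataset(simulationSpec(nOrganisms = 60, nFamilies = 50,
                                       nGenera = 6,
                                       traits = list(list(
                                         name = "Endospores",
                                         positiveFraction = 0.5,
                                         nCausal = 6, nCounterCausal = 0,
                                         pPos = 1, pNeg = 0))), seed = 29)
  prof <- normalizeToFrequencies(ds$counts)
  lab <- parseAnnotation(ds$annotation, "Endospores")@labels
  r1 <- repeatedKFoldEval(prof, lab, k = 5, reps = 3, lambda = 1, seed = 7)
  r2 <- repeatedKFoldEval(prof, lab, k = 5, reps = 3, lambda = 1, seed = 7)
  expect_equal(r1, r2)
  expect_equal(nrow(r1), 3)
  # strong planted signal -> high ranking quality
  expect_true(all(r1$auc_roc > 0.8))
  sm <- attr(r1, "summary")
  expect_true(all(sm$std >= 0))

  # perfectly separable archetypes -> aucROC 1 in every repetition
  set.seed(30)
  mkOrg <- function(hallmark) {
    cnt <- rpois(12, 2)
    cnt[hallmark] <- 100
    cnt
  }
  m <- cbind(sapply(1:20, function(i) mkOrg(1)),
             sapply(1:20, function(i) mkOrg(2)))
  colnames(m) <- sprintf("org%03d", 1:40)
  rownames(m) <- sprintf("SF%05d", 1:12)
  profS <- normalizeToFrequencies(DomainCountSet(m))
  labS <- stats::setNames(rep(c(1L, -1L), each = 20), colnames(m))
  rs <- repeatedKFoldEval(profS, labS, k = 5, reps = 3, lambda = 1,
                          seed = 7)
  expect_equal(rs$auc_roc, rep(1, 3))
  expect_equal(rs$harmonic_mean, rep(1, 3))
  expect_error(repeatedKFoldEval(prof, rep(1L, 60), k = 5, reps = 1),
               class = "pdValueError")
})

test_that("fold assignment keeps both classes in every fold", {
  lab <- c(rep(1L, 12), rep(-1L, 8))
  f <- makeStratifiedFolds(lab, k = 4, seed = 3)
  for (k in 1:4) {
    expect_true(all(c(-1L, 1L) %in% lab[f == k]))
  }
})

test_that("genus-confounded signal degrades under genus partitioning", {
  spec <- simulationSpec(nOrganisms = 120, nFamilies = 100, nGenera = 10,
                         traits = list(list(name = "Endospores",
                                            positiveFraction = 0.5,
                                            nCausal = 5,
                                            nCounterCausal = 0,
                                            pPos = 0.7, pNeg = 0.2)),
                         genusLabels = TRUE)
  ds <- generateDataset(spec, seed = 31)
  rep <- runValidationExperiment(ds$counts, ds$annotation, "Endospores",
                                 lambda = 1, reps = 10, seed = 31)
  expect_identical(rep$phenotype, c("Endospores", "average"))
  expect_lt(rep$harmonic_genus[1], rep$harmonic_random[1])
  expect_equal(rep$difference, rep$harmonic_genus - rep$harmonic_random)
  # single-class phenotype is skipped with a warning
  annot2 <- ds$annotation
  annot2$Endospores <- "yes"
  expect_warning(
    expect_error(runValidationExperiment(ds$counts, annot2, "Endospores",
                                         lambda = 1, reps = 2),
                 class = "pdValueError"),
    "single class|fewer than two")
})
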