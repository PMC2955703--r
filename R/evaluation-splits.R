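## Splitting protocols: random 70/30 partitions, genus-partitioned splits
## (all organisms of a genus go wholly to one side), stratified k-fold.
## Every split function is a pure function of its inputs and the seed.

#' Random train/validation partitions
#'
#' Draws `reps` independent partitions with `round(trainFraction * n)`
#' training examples each (default: the 20 x 70/30 protocol used for
#' validation and lambda selection).
#'
#' @param n number of examples.
#' @param reps number of partitions (default 20).
#' @param trainFraction training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list of `list(train =, validation =)` index vectors.
#' @export
makeRandomPartitions <- function(n, reps = 20, trainFraction = 0.7,
                                 seed = 1) {
  pdAssert(n >= 4L, "pdValueError", "need at least 4 examples to split")
  nTrain <- round(trainFraction * n)
  pdAssert(nTrain >= 1L && nTrain < n, "pdValueError",
           "train fraction leaves an empty train or validation set")
  withSeed(seed, lapply(seq_len(reps), function(r) {
    tr <- sort(sample.int(n, nTrain))
    list(train = tr, validation = setdiff(seq_len(n), tr))
  }))
}

#' Genus-partitioned train/validation splits
#'
#' Whole genera are assigned to train or validation so that no genus is
#' shared across the split — organisms from genera used for training are
#' never used for performance assessment. Genera are shuffled and added to
#' the validation side greedily until it holds at least
#' `validationFraction` of the organisms.
#'
#' @param genera character vector of per-organism genus labels.
#' @param reps number of splits (default 20, mirroring the random scheme).
#' @param validationFraction target validation fraction by organism count.
#' @param seed RNG seed.
#' @return list of `list(train =, validation =)` index vectors.
#' @export
makeGenusPartitions <- function(genera, reps = 20,
                                validationFraction = 0.3, seed = 1) {
  genera <- as.character(genera)
  ug <- unique(genera)
  pdAssert(length(ug) >= 2L, "pdValueError",
           "genus partitioning needs at least 2 distinct genera")
  n <- length(genera)
  target <- validationFraction * n
  withSeed(seed, lapply(seq_len(reps), function(r) {
    ord <- sample(ug)
    sizes <- table(genera)[ord]
    cum <- cumsum(sizes)
    k <- which(cum >= target)[1]
    if (is.na(k)) k <- length(ord)
    k <- min(k, length(ord) - 1L)  # keep the training side non-empty
    val <- which(genera %in% ord[seq_len(k)])
    list(train = setdiff(seq_len(n), val), validation = val)
  }))
}

#' Stratified k-fold assignment
#'
#' Assigns each example to one of `k` folds, separately within each class
#' so every fold holds both classes whenever class sizes permit.
#'
#' @param labels label vector (+1/-1 or class indices), no missing values.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment (1..k) per example.
#' @export
makeStratifiedFolds <- function(labels, k = 10, seed = 1) {
  pdAssert(all(table(labels) >= 2L), "pdValueError",
           "every class needs at least 2 members for k-fold evaluation")
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}
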