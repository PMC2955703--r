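# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force / generic numerical optimization) and
# share no code with the package internals they verify.

# Naive O(n^3) UPGMA: scan all active pairs for the minimum distance
# (lexicographically lowest pair on ties), merge at that height, and
# recompute distances as size-weighted averages. Returns hclust-style
# merge matrix (rows sorted) and heights.
naiveUPGMA <- function(D) {
  D <- as.matrix(D)
  m <- nrow(D)
  ids <- -seq_len(m)
  sizes <- rep(1, m)
  merge <- matrix(0L, m - 1L, 2L)
  height <- numeric(m - 1L)
  for (k in seq_len(m - 1L)) {
    n <- length(ids)
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (D[i, j] < best) {
          best <- D[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    merge[k, ] <- sort(c(ids[bi], ids[bj]))
    height[k] <- best
    newd <- (sizes[bi] * D[bi, ] + sizes[bj] * D[bj, ]) /
      (sizes[bi] + sizes[bj])
    keep <- setdiff(seq_len(n), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    ids <- c(ids[keep], k)
    sizes <- c(sizes[keep], sizes[bi] + sizes[bj])
  }
  list(merge = merge, height = height)
}

# Pair-counting AUC: fraction of positive/negative score pairs ranked
# correctly (ties count 1/2) -- the Mann-Whitney U form.
pairCountAUC <- function(scores, truth) {
  sp <- scores[truth == 1L]
  sn <- scores[truth == -1L]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

# Generic numerical minimizer of the balanced ridge objective, BFGS with
# the analytic gradient.
minimizeObjectiveBFGS <- function(X, y, b, lambda,
                                  w0 = rep(0, ncol(X))) {
  f <- function(w) sum(b * (y - as.numeric(X %*% w))^2) +
    lambda * sum(w^2)
  g <- function(w) {
    r <- y - as.numeric(X %*% w)
    as.numeric(-2 * crossprod(X, b * r) + 2 * lambda * w)
  }
  stats::optim(w0, f, g, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
}

# Closed-form primal solve of the stationarity system
# (X^t B_w X + lambda I) w = X^t B_w y  with B_w = diag(b),
# X given organisms x families.
primalSolve <- function(X, y, b, lambda) {
  A <- crossprod(X, X * b) + diag(lambda, ncol(X))
  as.numeric(solve(A, crossprod(X, b * y)))
}

# Random binary training problem with both classes guaranteed.
randomProblem <- function(n, d, seed) {
  set.seed(seed)
  X <- matrix(runif(n * d), n, d)
  y <- sample(c(-1L, 1L), n, replace = TRUE)
  if (length(unique(y)) == 1L) y[1] <- -y[1]
  rownames(X) <- sprintf("o%03d", seq_len(n))
  colnames(X) <- sprintf("SF%05d", seq_len(d))
  list(X = X, y = y)
}

# Random symmetric distance matrix with continuous (tie-free) entries.
randomDistMatrix <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 2)
  D <- D + t(D)
  dimnames(D) <- list(sprintf("L%02d", seq_len(n)),
                      sprintf("L%02d", seq_len(n)))
  D
}

# Cophenetic (merge-height) matrix of a LinkageTree.
upgmaCophenetic <- function(tree) {
  as.matrix(stats::cophenetic(tree@hc))
}

# Small DomainCountSet from a families x organisms matrix.
makeCountSet <- function(m, annotation = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("SF%05d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("org%03d", seq_len(ncol(m)))
  DomainCountSet(m, annotation = annotation)
}
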