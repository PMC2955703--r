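## Balanced regularized least-squares classification (RLSC).
##
## The balanced error function over N training profiles x_i with labels
## y_i in {-1, +1} is
##
##     E(w) = sum_i b_i (y_i - w . x_i)^2 + lambda ||w||^2,
##
## with b_i the inverse size of the class of example i, so each class
## contributes the same total weight regardless of imbalance. With a
## linear kernel K = X^t X the minimizer has the dual form
##
##     alpha = (K + lambda B)^{-1} y,   B = diag(1/b_i) = diag(class sizes),
##
## and the primal discriminant w = X alpha. Both routes must agree; the
## double inversion in B is deliberate and is pinned by the stationarity
## tests (K + lambda * diag(class sizes), not diag(1/class sizes)).

#' Per-example class-balancing weights
#'
#' `b[i] = 1 / |class(i)|`; the dual solve adds `lambda * diag(1/b)` (the
#' class sizes) to the kernel. Works for binary (+1/-1) and multi-class
#' (index) labels; missing labels are not allowed here.
#'
#' @param labels a [PhenotypeLabels-class] or an integer label vector.
#' @return a [BalanceWeights-class].
#' @export
#' @examples
#' balanceWeights(c(1L, 1L, 1L, -1L))@b
balanceWeights <- function(labels) {
  lab <- if (is(labels, "PhenotypeLabels")) labels@labels else labels
  lab <- lab[!is.na(lab)]
  pdAssert(length(lab) > 0L, "pdValueError", "no labeled examples")
  sizes <- table(lab)
  pdAssert(all(sizes >= 1L), "pdValueError", "empty class")
  cls <- as.character(lab)
  Bdiag <- as.numeric(sizes[cls])
  new("BalanceWeights", b = 1 / Bdiag, Bdiag = Bdiag)
}

#' Linear kernel between profile matrices
#'
#' `K[i, j]` is the dot product of profile i of `x` and profile j of `y`.
#' With `x == y` this is the training kernel `K = X^t X` of the dual RLSC
#' formulation: symmetric and positive semi-definite.
#'
#' @param x,y [ProfileMatrix-class] objects or organisms x families
#'   matrices with equal family dimension.
#' @return numeric matrix, `nrow(x)` x `nrow(y)`.
#' @export
linearKernel <- function(x, y = x) {
  xm <- if (is(x, "ProfileMatrix")) x@values else as.matrix(x)
  ym <- if (is(y, "ProfileMatrix")) y@values else as.matrix(y)
  pdAssert(ncol(xm) == ncol(ym), "pdDimensionError",
           "profile dimensionality differs: ", ncol(xm), " vs ", ncol(ym))
  tcrossprod(xm, ym)
}

## Symmetric solve of (K + lambda * diag(Bdiag)) A = Y via Cholesky; lambda
## > 0 and Bdiag > 0 guarantee positive definiteness for PSD K, so no
## jitter is added.
.rlscSolve <- function(K, Y, Bdiag, lambda) {
  M <- K + diag(lambda * Bdiag, nrow = nrow(K))
  ch <- tryCatch(chol(M), error = function(e) {
    pdStop("pdNumericalError",
           "kernel system is numerically singular; increase lambda")
  })
  backsolve(ch, backsolve(ch, Y, transpose = TRUE))
}

#' Train a balanced RLSC model
#'
#' Solves `(K + lambda B) alpha = y` on the training kernel via a symmetric
#' (Cholesky) factorization; never forms an explicit inverse. For
#' multi-class problems the label vector is replaced by the 0/1 indicator
#' matrix `Y = [z_1, ..., z_M]` and one dual weight column is obtained per
#' class ("classification by regression"). The primal discriminant
#' `w = X^t alpha` is computed and stored alongside.
#'
#' @param profiles a (typically scaled) [ProfileMatrix-class], or an
#'   organisms x families matrix.
#' @param labels a [PhenotypeLabels-class] or labeled integer vector
#'   (named if `profiles` has rownames). Missing labels drop the organism.
#' @param lambda regularization parameter, > 0.
#' @return an [RLSCModel-class].
#' @export
rlscTrain <- function(profiles, labels, lambda) {
  pdAssert(is.numeric(lambda) && length(lambda) == 1L && lambda > 0,
           "pdValueError", "lambda must be a single positive number")
  X <- if (is(profiles, "ProfileMatrix")) profiles@values else
    as.matrix(profiles)
  scaler <- if (is(profiles, "ProfileMatrix")) profiles@scaler else NULL

  if (is(labels, "PhenotypeLabels")) {
    lab <- labels@labels
    scheme <- labels@scheme
    classNames <- labels@classNames
    phenotype <- labels@phenotype
  } else {
    lab <- labels
    scheme <- if (all(stats::na.omit(labels) %in% c(-1L, 1L))) "binary"
              else "multiclass"
    classNames <- if (scheme == "binary") c("-1", "+1")
                  else as.character(seq_len(max(labels, na.rm = TRUE)))
    phenotype <- "unnamed"
  }
  if (!is.null(names(lab)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(lab)[!is.na(lab)])
    pdAssert(length(common) > 0L, "pdValueError",
             "no labeled organisms among the profiles")
    X <- X[common, , drop = FALSE]
    lab <- lab[common]
  } else {
    pdAssert(length(lab) == nrow(X), "pdDimensionError",
             "labels and profiles disagree in length")
    keep <- !is.na(lab)
    X <- X[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  pdAssert(length(unique(lab)) >= 2L, "pdValueError",
           "training requires at least two classes")

  bw <- balanceWeights(lab)
  if (scheme == "binary") {
    Y <- matrix(as.numeric(lab), ncol = 1L,
                dimnames = list(NULL, classNames[2]))
  } else {
    m <- length(classNames)
    Y <- matrix(0, nrow = length(lab), ncol = m,
                dimnames = list(NULL, classNames))
    Y[cbind(seq_along(lab), lab)] <- 1
  }
  K <- tcrossprod(X)
  alpha <- .rlscSolve(K, Y, bw@Bdiag, lambda)
  alpha <- matrix(alpha, ncol = ncol(Y), dimnames = list(rownames(X),
                                                         colnames(Y)))
  w <- crossprod(X, alpha)
  new("RLSCModel", alpha = alpha, lambda = lambda, X = X,
      discriminant = w, y = Y, classNames = classNames, scheme = scheme,
      phenotype = phenotype, scaler = scaler,
      familyIds = colnames(X) %||% as.character(seq_len(ncol(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction scores
#'
#' The score of a profile x is `sum_i alpha_i <x_i, x>`, identically the
#' dot product with the primal discriminant `w`. Test profiles must be
#' scaled with the *training* scaler. A model restored from disk (without
#' its training profiles) predicts through the stored primal discriminant.
#'
#' @param model an [RLSCModel-class].
#' @param profiles [ProfileMatrix-class] or matrix of test profiles.
#' @param form `"dual"` (default when training profiles are present) or
#'   `"primal"`.
#' @return named numeric vector of scores for binary models; an
#'   organisms x classes matrix for multi-class models.
#' @export
predictScores <- function(model, profiles, form = c("auto", "dual",
                                                    "primal")) {
  form <- match.arg(form)
  Xt <- if (is(profiles, "ProfileMatrix")) profiles@values else
    as.matrix(profiles)
  if (is.null(dim(Xt))) Xt <- matrix(Xt, nrow = 1L)
  pdAssert(ncol(Xt) == length(model@familyIds), "pdDimensionError",
           "test profiles have ", ncol(Xt), " families; model expects ",
           length(model@familyIds))
  if (form == "auto") {
    form <- if (nrow(model@X) > 0L) "dual" else "primal"
  }
  s <- if (form == "dual") {
    pdAssert(nrow(model@X) > 0L, "pdValueError",
             "model carries no training profiles; use the primal form")
    tcrossprod(Xt, model@X) %*% model@alpha
  } else {
    Xt %*% model@discriminant
  }
  if (model@scheme == "binary") {
    stats::setNames(as.numeric(s), rownames(Xt))
  } else {
    s
  }
}

#' Decision rule on scores
#'
#' Binary: +1 if score > 0 else -1 (a score of exactly 0 classifies as
#' negative). Multi-class: argmax over the class columns, ties going to
#' the lower class index.
#'
#' @param scores numeric vector (binary) or matrix (multi-class).
#' @return integer labels (+1/-1) or class indices.
#' @export
classifyScores <- function(scores) {
  if (is.matrix(scores) && ncol(scores) > 1L) {
    as.integer(apply(scores, 1L, which.max))
  } else {
    ifelse(as.numeric(scores) > 0, 1L, -1L)
  }
}

#' Balanced RLSC objective (test oracle)
#'
#' Evaluates `E(w) = sum_i b_i (y_i - w . x_i)^2 + lambda ||w||^2`. Used to
#' verify trained discriminants against independent minimizers.
#'
#' @param w numeric weight vector (length d).
#' @param X organisms x families matrix.
#' @param y numeric labels (+1/-1).
#' @param b balancing factors (see [balanceWeights()]).
#' @param lambda regularization parameter.
#' @return scalar objective value.
#' @export
rlscObjective <- function(w, X, y, b, lambda) {
  r <- as.numeric(y) - as.numeric(X %*% w)
  sum(b * r^2) + lambda * sum(w^2)
}

#' Recover the primal discriminant
#'
#' `w = X^t alpha`: a single d-dimensional weight vector per class that
#' turns phenotype prediction into one dot product per organism.
#'
#' @param model an [RLSCModel-class].
#' @return a [Discriminant-class] (weights d x M, rownames = family ids).
#' @export
primalDiscriminant <- function(model) {
  w <- if (nrow(model@X) > 0L) {
    pdAssert(nrow(model@X) == nrow(model@alpha), "pdDimensionError",
             "alpha length does not match training profiles")
    crossprod(model@X, model@alpha)
  } else {
    model@discriminant
  }
  rownames(w) <- model@familyIds
  cls <- if (model@scheme == "binary") model@classNames[2] else
    model@classNames
  new("Discriminant", weights = w, classNames = cls)
}
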