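## Internal utilities: classed conditions, seed scoping, report rounding.

## All user-facing errors carry a subclass of "pdError" so callers (and the
## command-line layer) can map failure modes to exit codes without matching
## message text.
pdStop <- function(class, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "pdError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

pdAssert <- function(ok, class, ...) {
  if (!isTRUE(ok)) pdStop(class, ...)
  invisible(TRUE)
}

## Evaluate `code` under `seed` without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Report tables are rounded to 3 decimals with ties going away from zero
#' (0.0005 -> 0.001), the convention used for the printed result tables,
#' rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(0.8935, 3)
roundHalfUp <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Sample (N-1 denominator) column standard deviations; a single row fits
## std 0 on every dimension (degenerate but defined).
colSds <- function(m) {
  n <- nrow(m)
  if (n < 2L) {
    return(stats::setNames(numeric(ncol(m)), colnames(m)))
  }
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = n))^2) / (n - 1))
}

fmtNum <- function(x) sprintf("%.10g", x)
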