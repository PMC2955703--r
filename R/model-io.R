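## Model serialization: one self-describing versioned JSON file storing
## the dual weights, lambda, class names, scaler stds and the family-id
## order. Doubles are written with 17 significant digits so the round
## trip is bit-exact; matrices are stored column-major as flat
## vectors plus dimensions.

.FORMAT <- "phenoDomain/rlsc-model"
.FORMAT_VERSION <- 1L

.packMatrix <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), data = as.numeric(m),
       rownames = rownames(m), colnames = colnames(m))
}

.unpackMatrix <- function(p) {
  matrix(as.numeric(p$data), nrow = p$nrow, ncol = p$ncol,
         dimnames = list(
           if (length(p$rownames)) as.character(p$rownames) else NULL,
           if (length(p$colnames)) as.character(p$colnames) else NULL))
}

#' Serialize / restore an RLSC model
#'
#' `writeModel()` stores everything deployment needs — the primal
#' discriminant, the dual weights, lambda, class names, the scaler
#' standard deviations and the family-id order — in one versioned JSON
#' file; `readModel()` restores a model that predicts via the primal
#' discriminant. The round trip is bit-exact.
#'
#' @param model an [RLSCModel-class].
#' @param path file path.
#' @return `writeModel`: `path`, invisibly; `readModel`: an
#'   [RLSCModel-class] without training profiles.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    format = .FORMAT,
    version = .FORMAT_VERSION,
    phenotype = model@phenotype,
    scheme = model@scheme,
    classNames = as.list(model@classNames),
    lambda = model@lambda,
    familyIds = as.list(model@familyIds),
    alpha = .packMatrix(model@alpha),
    discriminant = .packMatrix(model@discriminant),
    scalerSds = if (is(model@scaler, "ScalingModel"))
      as.numeric(model@scaler@sds) else NULL,
    scalerNFit = if (is(model@scaler, "ScalingModel"))
      model@scaler@nFit else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  pdAssert(file.exists(path), "pdFormatError", "file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  pdAssert(identical(obj$format, .FORMAT), "pdFormatError",
           "not a phenoDomain model file: ", path)
  pdAssert(obj$version <= .FORMAT_VERSION, "pdFormatError",
           "model file version ", obj$version, " is newer than supported")
  famIds <- as.character(unlist(obj$familyIds))
  scaler <- NULL
  if (!is.null(obj$scalerSds)) {
    scaler <- new("ScalingModel",
                  sds = stats::setNames(as.numeric(obj$scalerSds), famIds),
                  nFit = as.integer(obj$scalerNFit))
  }
  w <- .unpackMatrix(obj$discriminant)
  new("RLSCModel",
      alpha = .unpackMatrix(obj$alpha),
      lambda = as.numeric(obj$lambda),
      X = matrix(numeric(0), nrow = 0L, ncol = nrow(w)),
      discriminant = w,
      y = matrix(numeric(0), nrow = 0L, ncol = ncol(w)),
      classNames = as.character(unlist(obj$classNames)),
      scheme = obj$scheme,
      phenotype = obj$phenotype,
      scaler = scaler,
      familyIds = famIds)
}
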