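#' @include AllClasses.R
NULL

#' Accessors
#'
#' `domainCounts()` returns the families x organisms count matrix;
#' `familyIds()` / `organismIds()` the identifier vectors;
#' `profileValues()` the organisms x families profile matrix;
#' `isScaled()` whether std scaling was applied; `scalerOf()` the fitted
#' scaler of a profile matrix or model.
#'
#' @param x a phenoDomain object.
#' @return matrix or character/logical vector as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("domainCounts", function(x) standardGeneric("domainCounts"))

#' @rdname accessors
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname accessors
#' @export
setGeneric("organismIds", function(x) standardGeneric("organismIds"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname accessors
#' @export
setGeneric("scalerOf", function(x) standardGeneric("scalerOf"))

#' @rdname accessors
#' @export
setMethod("domainCounts", "DomainCountSet",
          function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("familyIds", "DomainCountSet", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("familyIds", "RLSCModel", function(x) x@familyIds)

#' @rdname accessors
#' @export
setMethod("familyIds", "ProfileMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("organismIds", "DomainCountSet", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("organismIds", "ProfileMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("profileValues", "ProfileMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("isScaled", "ProfileMatrix", function(x) x@scaled)

#' @rdname accessors
#' @export
setMethod("scalerOf", "ProfileMatrix", function(x) x@scaler)

#' @rdname accessors
#' @export
setMethod("scalerOf", "RLSCModel", function(x) x@scaler)

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d organisms x %d families (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@scaled) "unit-std scaled" else "relative frequencies"))
})

setMethod("show", "ScalingModel", function(object) {
  cat(sprintf("ScalingModel: %d dimensions (%d with std = 0), fit on %d organisms\n",
              length(object@sds), sum(object@sds == 0), object@nFit))
})

setMethod("show", "PhenotypeLabels", function(object) {
  lab <- object@labels
  cat(sprintf("PhenotypeLabels '%s' (%s): %d labeled, %d missing\n",
              object@phenotype, object@scheme,
              sum(!is.na(lab)), sum(is.na(lab))))
  if (object@scheme == "binary") {
    cat(sprintf("  +1 ('%s'): %d   -1 ('%s'): %d\n",
                object@classNames[2], sum(lab == 1L, na.rm = TRUE),
                object@classNames[1], sum(lab == -1L, na.rm = TRUE)))
  } else {
    tab <- table(factor(lab, levels = seq_along(object@classNames),
                        labels = object@classNames))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  }
})

setMethod("show", "RLSCModel", function(object) {
  cat(sprintf("RLSCModel (%s) for '%s': %d training examples, d = %d, lambda = %g\n",
              object@scheme, object@phenotype, nrow(object@alpha),
              length(object@familyIds), object@lambda))
})

setMethod("show", "Discriminant", function(object) {
  cat(sprintf("Discriminant: d = %d, %d class column(s)\n",
              nrow(object@weights), ncol(object@weights)))
})

setMethod("show", "RankedDomains", function(object) {
  cat(sprintf("RankedDomains: %d indicative, %d counter-indicative (n = %d)\n",
              nrow(object@indicative), nrow(object@counterIndicative),
              object@n))
})

setMethod("show", "LinkageTree", function(object) {
  cat(sprintf("LinkageTree (UPGMA): %d leaves, max merge height %.4g\n",
              length(object@labels), max(object@heights)))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d organisms, %d families, %d genera, %d trait(s), noise %.2f\n",
              object@nOrganisms, object@nFamilies, object@nGenera,
              length(object@traits), object@labelNoise))
})
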