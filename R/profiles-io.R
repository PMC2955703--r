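## Reading and writing the count-matrix and annotation CSV layouts.
##
## Count matrix layout: header row of organism ids, one row per family with
## the family id in the first field (PF00001... order for the pfam23
## dialect). Readers tolerate CRLF line endings and a UTF-8 BOM.

.dialectDims <- c(pfam23 = 10797L, cog = 5665L)

#' Read a domain/COG count matrix
#'
#' @param path CSV file: first column family ids, remaining columns one per
#'   organism, header row of organism ids.
#' @param dialect `"pfam23"` enforces the 10797 Pfam-A v23.0 families,
#'   `"cog"` the 5665 COG clusters; `"generic"` accepts any dimension.
#' @return a [DomainCountSet-class].
#' @export
readCountMatrix <- function(path, dialect = c("generic", "pfam23", "cog")) {
  dialect <- match.arg(dialect)
  pdAssert(file.exists(path), "pdFormatError", "file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM")
  pdAssert(ncol(df) >= 2L, "pdFormatError",
           "count matrix needs a family-id column and >= 1 organism column")
  fam <- as.character(df[[1]])
  orgs <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(orgs),
              dimnames = list(fam, orgs))
  for (j in seq_along(orgs)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      v <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(v) & !is.na(col) & trimws(col) != "")
      if (length(bad)) {
        pdStop("pdFormatError", "non-numeric count at family '", fam[bad[1]],
               "', organism '", orgs[j], "'")
      }
      col <- v
    }
    m[, j] <- col
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    pdStop("pdFormatError", "missing count at family '", fam[idx[1]],
           "', organism '", orgs[idx[2]], "'")
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    pdStop("pdFormatError", "negative count at family '", fam[neg[1, 1]],
           "', organism '", orgs[neg[1, 2]], "'")
  }
  if (dialect != "generic") {
    d <- .dialectDims[[dialect]]
    pdAssert(nrow(m) == d, "pdDimensionError",
             "dialect '", dialect, "' requires ", d, " family rows, got ",
             nrow(m))
  }
  DomainCountSet(m)
}

#' Write a count matrix in the standard CSV layout
#'
#' @param x a [DomainCountSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path) {
  m <- domainCounts(x)
  df <- data.frame(family_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an organism annotation table
#'
#' Expected columns: `organism_id`, `organism_name`, `status`, then one
#' column per phenotype holding annotation strings ("yes"/"no", "+"/"-",
#' "motile"/"non-motile", ...). Empty strings mean unannotated.
#'
#' @param path CSV file.
#' @return a `data.frame` (phenotype column names kept verbatim).
#' @export
readAnnotation <- function(path) {
  pdAssert(file.exists(path), "pdFormatError", "file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", colClasses = "character")
  pdAssert(all(c("organism_id", "organism_name") %in% colnames(df)),
           "pdFormatError",
           "annotation table must have organism_id and organism_name columns")
  pdAssert(!anyDuplicated(df$organism_id), "pdFormatError",
           "duplicate organism_id in annotation table")
  df
}

#' Write an annotation table
#' @param annotation `data.frame` as returned by [readAnnotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
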