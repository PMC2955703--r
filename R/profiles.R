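## Profile construction: frequency normalization, per-dimension std
## scaling, deduplication of identical count profiles, label parsing.

#' Normalize counts to relative domain frequencies
#'
#' Each organism's count vector is divided by its total so that every
#' profile row sums to 1: the learner consumes domain *frequencies*, which
#' makes profiles comparable across genomes of different size (and, for
#' draft genomes, sequencing depth).
#'
#' @param counts a [DomainCountSet-class].
#' @return an unscaled [ProfileMatrix-class] (organisms x families).
#' @export
normalizeToFrequencies <- function(counts) {
  m <- t(domainCounts(counts))
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero)) {
    pdStop("pdDegenerateError", "organism '", rownames(m)[zero[1]],
           "' has an all-zero domain profile")
  }
  new("ProfileMatrix", values = m / tot, scaled = FALSE, scaler = NULL)
}

#' Fit / apply per-dimension unit-std scaling
#'
#' Every dimension of the frequency profile space with a non-zero standard
#' deviation is normalized to unit sample standard deviation (denominator
#' N-1); std-0 dimensions are left unchanged. Fit the scaler on training
#' organisms only and apply it to validation/test profiles, so no
#' information leaks across the split.
#'
#' @param profiles an unscaled [ProfileMatrix-class].
#' @param subset organism ids or indices to fit on (default: all).
#' @return `fitScaler`: a [ScalingModel-class]; `applyScaler`: a scaled
#'   [ProfileMatrix-class].
#' @export
fitScaler <- function(profiles, subset = NULL) {
  pdAssert(is(profiles, "ProfileMatrix"), "pdValueError",
           "profiles must be a ProfileMatrix")
  pdAssert(!profiles@scaled, "pdValueError",
           "scaler must be fitted on unscaled profiles")
  v <- profiles@values
  if (!is.null(subset)) {
    v <- v[subset, , drop = FALSE]
  }
  pdAssert(nrow(v) >= 1L, "pdValueError", "scaler subset is empty")
  new("ScalingModel", sds = colSds(v), nFit = nrow(v))
}

#' @rdname fitScaler
#' @param scaler a [ScalingModel-class].
#' @export
applyScaler <- function(profiles, scaler) {
  v <- profileValues(profiles)
  pdAssert(length(scaler@sds) == ncol(v), "pdDimensionError",
           "scaler has ", length(scaler@sds), " dimensions but profiles have ",
           ncol(v))
  s <- scaler@sds
  div <- ifelse(s > 0, s, 1)
  out <- sweep(v, 2L, div, "/")
  new("ProfileMatrix", values = out, scaled = TRUE, scaler = scaler)
}

#' Reduce organisms with identical count profiles to one representative
#'
#' Databases contain many strains with identical detected domain content;
#' duplicates would otherwise be counted several times during training and
#' evaluation. The first organism in input order is kept as the
#' representative.
#'
#' @param counts a [DomainCountSet-class].
#' @return `list(counts = reduced DomainCountSet, map = named character)`
#'   where `map[dropped] == representative`.
#' @export
deduplicateProfiles <- function(counts) {
  m <- domainCounts(counts)
  key <- apply(m, 2L, paste, collapse = "\r")
  first <- match(key, key)
  keep <- which(first == seq_along(key))
  dropped <- which(first != seq_along(key))
  map <- stats::setNames(colnames(m)[first[dropped]], colnames(m)[dropped])
  list(counts = counts[, keep], map = map)
}

.defaultPhenotypeMap <- list(
  "Endospores"         = c(negative = "no", positive = "yes"),
  "Gram stain"         = c(negative = "-", positive = "+"),
  "Motility"           = c(negative = "non-motile", positive = "motile"),
  "Oxygen Requirement" = c(negative = "anaerobic", positive = "aerobic")
)

#' Parse phenotype annotation strings into labels
#'
#' Binary scheme: the configured positive string maps to +1, the negative
#' string to -1, anything else (including the empty string and, e.g.,
#' "facultative" oxygen requirement) to missing. Multi-class scheme: every
#' distinct configured (or observed) trait string becomes a class index;
#' empty strings are missing. Matching is case-insensitive after trimming.
#'
#' Built-in binary mappings exist for the four standard phenotype columns:
#' "Endospores" (yes/no), "Gram stain" (+/-), "Motility"
#' (motile/non-motile) and "Oxygen Requirement" (aerobic/anaerobic).
#'
#' @param annotation annotation `data.frame` (see [readAnnotation()]).
#' @param phenotype annotation column name.
#' @param scheme `"binary"` or `"multiclass"`.
#' @param positive,negative annotation strings for the binary scheme
#'   (defaults from the built-in mapping).
#' @param classes optional class strings for the multiclass scheme.
#' @return a [PhenotypeLabels-class].
#' @export
parseAnnotation <- function(annotation, phenotype,
                            scheme = c("binary", "multiclass"),
                            positive = NULL, negative = NULL,
                            classes = NULL) {
  scheme <- match.arg(scheme)
  pdAssert(phenotype %in% colnames(annotation), "pdLookupError",
           "phenotype column '", phenotype, "' not found in annotation")
  raw <- tolower(trimws(as.character(annotation[[phenotype]])))
  raw[is.na(raw)] <- ""
  ids <- as.character(annotation$organism_id)

  if (scheme == "binary") {
    if (is.null(positive) || is.null(negative)) {
      map <- .defaultPhenotypeMap[[phenotype]]
      pdAssert(!is.null(map), "pdValueError",
               "no built-in label mapping for phenotype '", phenotype,
               "'; supply positive= and negative=")
      if (is.null(positive)) positive <- map[["positive"]]
      if (is.null(negative)) negative <- map[["negative"]]
    }
    pos <- tolower(trimws(positive))
    neg <- tolower(trimws(negative))
    lab <- rep(NA_integer_, length(raw))
    lab[raw == pos] <- 1L
    lab[raw == neg] <- -1L
    new("PhenotypeLabels", phenotype = phenotype,
        labels = stats::setNames(lab, ids),
        classNames = c(negative, positive), scheme = "binary")
  } else {
    if (is.null(classes)) {
      classes <- sort(unique(raw[raw != ""]))
    } else {
      classes <- tolower(trimws(classes))
    }
    lab <- match(raw, classes)
    lab[raw == ""] <- NA_integer_
    new("PhenotypeLabels", phenotype = phenotype,
        labels = stats::setNames(as.integer(lab), ids),
        classNames = classes, scheme = "multiclass")
  }
}

#' Extract the genus from an organism display name
#'
#' Returns the first whitespace-delimited token, case-normalized (initial
#' capital, rest lower). Note the rule is applied literally, so names with
#' a "Candidatus" prefix yield "Candidatus".
#'
#' @param name character vector of organism display names.
#' @return character vector of genus names.
#' @export
#' @examples
#' extractGenus("Bacillus cereus 03BB102")
extractGenus <- function(name) {
  pdAssert(all(nzchar(trimws(name))), "pdValueError",
           "organism name must be non-empty")
  tok <- vapply(strsplit(trimws(name), "\\s+"), `[[`, "", 1L)
  paste0(toupper(substring(tok, 1L, 1L)), tolower(substring(tok, 2L)))
}
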