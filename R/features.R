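## Discriminative-feature analysis: ranking domain families by primal
## weight, phylogenetic (presence/absence) profiles, UPGMA clustering with
## correlation distance, cluster coloring, Newick export.

#' Rank discriminative domain families
#'
#' Extracts the families with the `n` largest positive (indicative) and
#' most negative (counter-indicative) weights from a primal discriminant.
#' Only strictly positive / strictly negative weights qualify, so either
#' list may be shorter than `n`. Equal weights are broken by lower family
#' index (input order).
#'
#' @param w a [Discriminant-class], or a numeric weight vector.
#' @param familyIds family ids (defaults to names/rownames of `w`).
#' @param n list length (default 50).
#' @param groupCounts optional named integer vector of phylogenetic-group
#'   counts per family (see [countPhylogroups()]); added as a
#'   `group_count` column.
#' @return a [RankedDomains-class].
#' @export
rankDomains <- function(w, familyIds = NULL, n = 50, groupCounts = NULL) {
  pdAssert(n > 0, "pdValueError", "n must be positive")
  if (is(w, "Discriminant")) {
    pdAssert(ncol(w@weights) == 1L, "pdValueError",
             "rank one class column at a time")
    if (is.null(familyIds)) familyIds <- rownames(w@weights)
    w <- as.numeric(w@weights[, 1L])
  }
  if (is.null(familyIds)) familyIds <- names(w)
  pdAssert(!is.null(familyIds) && length(familyIds) == length(w),
           "pdDimensionError", "familyIds must match the discriminant length")

  pick <- function(idx, decreasing) {
    o <- idx[order(w[idx] * if (decreasing) -1 else 1, idx)]
    o <- utils::head(o, n)
    df <- data.frame(rank = seq_along(o), family_id = familyIds[o],
                     weight = w[o], stringsAsFactors = FALSE)
    if (!is.null(groupCounts)) {
      df$group_count <- as.integer(groupCounts[df$family_id])
    }
    df
  }
  new("RankedDomains",
      indicative = pick(which(w > 0), TRUE),
      counterIndicative = pick(which(w < 0), FALSE),
      n = as.integer(n))
}

#' Phylogenetic profiles of selected families
#'
#' The absence/presence pattern of each selected family across all
#' organisms: entry 1 iff the family's count is > 0.
#'
#' @param counts a [DomainCountSet-class].
#' @param families family ids to profile.
#' @return binary matrix, families x organisms.
#' @export
phyloProfiles <- function(counts, families) {
  m <- domainCounts(counts)
  missing <- setdiff(families, rownames(m))
  pdAssert(length(missing) == 0L, "pdLookupError",
           "unknown family id(s): ", paste(missing, collapse = ", "))
  (m[families, , drop = FALSE] > 0) + 0
}

#' Correlation distance between two phylogenetic profiles
#'
#' `1 - Pearson correlation`, in \[0, 2\]. A constant profile (all-absent
#' or all-present) has undefined correlation; its distance to anything is
#' defined as 1 (uninformative).
#'
#' @param p,q binary (or numeric) vectors of equal length >= 2.
#' @return numeric distance.
#' @export
correlationDistance <- function(p, q) {
  pdAssert(length(p) == length(q), "pdValueError",
           "profile lengths differ")
  pdAssert(length(p) >= 2L, "pdValueError", "profiles need length >= 2")
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    return(1)
  }
  1 - stats::cor(p, q)
}

#' Pairwise correlation-distance matrix
#'
#' @param profiles rows = families (as from [phyloProfiles()]).
#' @return a `dist` object over the rows.
#' @export
correlationDistMatrix <- function(profiles) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- correlationDistance(profiles[i, ],
                                                profiles[j, ])
    }
  }
  stats::as.dist(d)
}

#' UPGMA clustering
#'
#' Average-linkage (UPGMA) agglomeration: repeatedly merge the closest
#' pair of clusters at a height equal to their distance, replacing them by
#' a cluster whose distance to any other is the size-weighted average of
#' the members' distances. Delegates to [stats::hclust] with
#' `method = "average"`.
#'
#' @param d a `dist` object or symmetric non-negative distance matrix.
#' @return a [LinkageTree-class].
#' @export
upgmaTree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    pdAssert(isSymmetric(unname(d)), "pdValueError",
             "distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  pdAssert(all(is.finite(d)), "pdValueError", "non-finite distance")
  pdAssert(all(d >= 0), "pdValueError", "distances must be non-negative")
  hc <- stats::hclust(d, method = "average")
  labs <- hc$labels %||% as.character(seq_len(attr(d, "Size")))
  new("LinkageTree", merges = hc$merge, heights = hc$height,
      labels = labs, hc = hc)
}

#' Color clusters below a relative height threshold
#'
#' Cuts the dendrogram at `threshold` times the maximum merge height (the
#' conventional 70% default): leaves in the same subtree below the cut
#' share a cluster; singleton subtrees receive a null (`NA`) color.
#'
#' @param tree a [LinkageTree-class].
#' @param threshold fraction of the maximum merge height (default 0.7).
#' @return `data.frame` with columns `family_id`, `cluster` (the cut
#'   partition) and `color` (`NA` for singletons).
#' @export
colorClusters <- function(tree, threshold = 0.7) {
  cutH <- threshold * max(tree@heights)
  grp <- stats::cutree(tree@hc, h = cutH)
  sizes <- table(grp)
  color <- ifelse(sizes[as.character(grp)] > 1L, grp, NA_integer_)
  data.frame(family_id = tree@labels, cluster = as.integer(grp),
             color = as.integer(color), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Count phylogenetic groups containing a family
#'
#' Number of distinct phylogenetic groups (e.g. NCBI phyla) with at least
#' one organism in which the family occurs — the "# groups" column of the
#' ranked-domain reports.
#'
#' @param counts a [DomainCountSet-class].
#' @param family family id.
#' @param groupMap named character vector, organism id -> group.
#' @return integer group count.
#' @export
countPhylogroups <- function(counts, family, groupMap) {
  m <- domainCounts(counts)
  pdAssert(family %in% rownames(m), "pdLookupError",
           "unknown family id: ", family)
  orgs <- colnames(m)
  unmapped <- setdiff(orgs, names(groupMap))
  pdAssert(length(unmapped) == 0L, "pdLookupError",
           "organisms without phylogroup mapping: ",
           paste(utils::head(unmapped, 3), collapse = ", "))
  present <- orgs[m[family, ] > 0]
  length(unique(groupMap[present]))
}

#' Export a linkage tree as Newick text
#'
#' Branch lengths derive from merge heights: a leaf's branch equals its
#' parent's height, an internal node's branch the height difference to its
#' parent. The result parses back to the same topology and heights.
#'
#' @param tree a [LinkageTree-class].
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
exportNewick <- function(tree, path = NULL) {
  merges <- tree@merges
  heights <- tree@heights
  labs <- tree@labels
  branch <- function(child, parentHeight) {
    if (child < 0L) {
      paste0(labs[-child], ":", fmtNum(parentHeight))
    } else {
      paste0(subtree(child), ":", fmtNum(parentHeight - heights[child]))
    }
  }
  subtree <- function(k) {
    paste0("(", branch(merges[k, 1L], heights[k]), ",",
           branch(merges[k, 2L], heights[k]), ")")
  }
  txt <- paste0(subtree(nrow(merges)), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
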