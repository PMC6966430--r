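# Cross-platform concordance: Jaccard similarity at gene / pathway /
# system level, and Euclidean clustering of condition meta-z profiles.

#' Jaccard similarity of two sets
#'
#' `|intersection| / |union|`. Two empty sets return 0 (with a warning)
#' rather than NaN so report aggregation stays total.
#'
#' @param s_i,s_j Character vectors (treated as sets).
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(s_i, s_j) {
  s_i <- unique(s_i); s_j <- unique(s_j)
  u <- length(union(s_i, s_j))
  if (u == 0L) {
    warning("jaccard: both sets empty; returning 0")
    return(0)
  }
  length(intersect(s_i, s_j)) / u
}

#' Bundle one platform's results for concordance
#'
#' @param degs Character vector of DEG ids (both directions pooled).
#' @param pathways Character vector of significant pathway ids.
#' @param systems Character vector of significant system ids.
#' @return A `ConcordanceBundle` list.
#' @export
concordance_bundle <- function(degs, pathways, systems) {
  structure(list(degs = unique(degs), pathways = unique(pathways),
                 systems = unique(systems)),
            class = "ConcordanceBundle")
}

#' Significant systems of an enrichment profile
#'
#' The pathway-level significance rule (raw p < 0.05) has no standard
#' system analogue; a system is called significant here when its meta-z exceeds
#' the one-sided normal 5% quantile (z > qnorm(0.95) ~ 1.6449),
#' mirroring the pathway rule on the z scale. The threshold is exposed.
#'
#' @param profile An `EnrichmentProfile`.
#' @param z_threshold Meta-z cutoff, default `qnorm(0.95)`.
#' @return Character vector of system ids.
#' @export
significant_systems <- function(profile, z_threshold = stats::qnorm(0.95)) {
  stopifnot(inherits(profile, "EnrichmentProfile"))
  profile$systems$id[profile$systems$meta_z > z_threshold]
}

#' Per-level Jaccard concordance between two platforms
#'
#' Compares the DEG sets, significant-pathway sets, and
#' significant-system sets of the two platforms for one condition.
#'
#' @param bundle_i,bundle_j `ConcordanceBundle`s (e.g. microarray vs
#'   RNA-seq of the same genotype/diet contrast).
#' @return Named numeric vector: `gene`, `pathway`, `system` Jaccard
#'   values.
#' @export
concordance_report <- function(bundle_i, bundle_j) {
  stopifnot(inherits(bundle_i, "ConcordanceBundle"),
            inherits(bundle_j, "ConcordanceBundle"))
  levels <- c("degs", "pathways", "systems")
  for (b in list(bundle_i, bundle_j)) {
    if (!all(levels %in% names(b)) ||
        any(vapply(b[levels], is.null, logical(1)))) {
      stop("concordance bundle missing a level", call. = FALSE)
    }
  }
  c(gene = jaccard(bundle_i$degs, bundle_j$degs),
    pathway = jaccard(bundle_i$pathways, bundle_j$pathways),
    system = jaccard(bundle_i$systems, bundle_j$systems))
}

#' Hierarchical clustering of condition meta-z profiles
#'
#' Agglomerative clustering of the conditions (rows) of a
#' conditions-by-systems meta-z matrix using Euclidean distance; the
#' linkage method defaults to average and a flat 2-group cut is returned
#' alongside the dendrogram.
#'
#' @param profile_matrix Numeric matrix, conditions in rows (rownames
#'   required), systems in columns; no missing cells.
#' @param linkage `"average"` (default), `"single"`, `"complete"`, or
#'   `"ward.D2"`.
#' @param k Number of flat groups to cut, default 2.
#' @return List with `hclust` (the stats::hclust tree) and `groups`
#'   (named membership vector from [stats::cutree()]).
#' @export
cluster_conditions <- function(profile_matrix,
                               linkage = c("average", "single",
                                           "complete", "ward.D2"),
                               k = 2) {
  linkage <- match.arg(linkage)
  profile_matrix <- as.matrix(profile_matrix)
  if (nrow(profile_matrix) < 2L) {
    stop("cluster_conditions: need at least 2 conditions", call. = FALSE)
  }
  if (is.null(rownames(profile_matrix)) ||
      anyDuplicated(rownames(profile_matrix))) {
    stop("cluster_conditions: unique condition rownames required",
         call. = FALSE)
  }
  if (anyNA(profile_matrix)) {
    stop("cluster_conditions: missing cells in profile matrix",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(profile_matrix, method = "euclidean"),
                      method = linkage)
  list(hclust = hc, groups = stats::cutree(hc, k = k))
}
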