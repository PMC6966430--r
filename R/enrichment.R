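#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing at least `x` DEGs in a pathway of `n` genes
#' when `M` DEGs are drawn from a universe of `N` annotated genes:
#' `p = sum_{i=x}^{min(M,n)} C(M,i) C(N-M,n-i) / C(N,n)`.
#' Evaluated through the stable log-space tail of the hypergeometric
#' distribution; `x = 0` gives exactly 1.
#'
#' @param N Universe size (genes in the annotation).
#' @param M Number of DEGs (one direction) within the universe.
#' @param n Pathway size within the universe.
#' @param x Overlap count (DEGs in the pathway).
#' @return Upper-tail p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, M, n, x) {
  for (v in list(N = N, M = M, n = n, x = x)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop("domain error: N, M, n, x must be single nonnegative integers",
           call. = FALSE)
    }
  }
  if (n > N || M > N) {
    stop("domain error: pathway size and DEG count cannot exceed the universe",
         call. = FALSE)
  }
  if (x > min(M, n)) {
    stop("domain error: overlap x exceeds min(M, n)", call. = FALSE)
  }
  stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
}

#' Transform a p-value to a standard-normal z-score
#'
#' `z = qnorm(1 - p)`: small p-values map to large positive z. To keep z
#' finite at both degenerate extremes (perfect enrichment, empty DEG
#' sets giving p = 1), p is clamped into `[clamp, 1 - clamp]` before the
#' transformation.
#'
#' @param p P-value(s) in (0, 1].
#' @param clamp Small positive clamp, default 1e-16.
#' @return z-score(s), strictly decreasing in p on the unclamped range.
#' @export
p_to_z <- function(p, clamp = 1e-16) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("domain error: p must lie in (0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, clamp), 1 - clamp)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Directional pathway enrichment for one contrast
#'
#' Runs the hypergeometric upper-tail test separately for the up- and
#' down-regulated DEG sets of a contrast against every pathway. The
#' background is the annotation universe: DEGs absent from the annotation
#' are dropped from `M` and the overlap, with the dropped count reported.
#' Pathways with p < `alpha` are flagged significant. A per-pathway
#' direction-collapsed z is attached according to `combine`.
#'
#' @param contrast A `ContrastResult`.
#' @param gene_sets A `PathwayGeneSets`.
#' @param hierarchy Optional `AnnotationHierarchy`; when supplied, every
#'   scored pathway must be resolvable in it.
#' @param alpha Significance level on the raw p-value, default 0.05.
#' @param clamp Clamp forwarded to [p_to_z()].
#' @param combine Direction-collapse rule for the per-pathway combined z:
#'   `"max"` (default: the more significant direction — robust because a
#'   strongly regulated pathway looks *depleted* to the opposite
#'   direction's test, whose large negative z would cancel the signal
#'   under summation), `"sum"`, or `"signed"` (up z minus down z). Note
#'   the max rule is biased upward by about +0.56 per pathway under the
#'   null, so meta-z values aggregated from it sit high; system-level
#'   significance calls based on a normal quantile are correspondingly
#'   liberal.
#' @return An `EnrichmentResult`: `$pathways` (one row per pathway x
#'   direction with n, x, M, N, p, z, significant), `$combined` (one row
#'   per pathway), `$dropped` counts, and the parameters used.
#' @export
enrich_contrast <- function(contrast, gene_sets, hierarchy = NULL,
                            alpha = 0.05, clamp = 1e-16,
                            combine = c("max", "sum", "signed")) {
  stopifnot(inherits(contrast, "ContrastResult"),
            inherits(gene_sets, "PathwayGeneSets"))
  combine <- match.arg(combine)
  if (length(gene_sets$sets) == 0L || gene_sets$N == 0L) {
    stop("empty annotation: no pathways or empty universe", call. = FALSE)
  }
  if (!is.null(hierarchy)) {
    missing <- setdiff(names(gene_sets$sets), names(hierarchy$pathway_parent))
    if (length(missing)) {
      stop("pathway(s) missing from hierarchy: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  universe <- gene_sets$universe
  N <- gene_sets$N
  ids <- names(gene_sets$sets)
  sizes <- lengths(gene_sets$sets)

  one_direction <- function(degs, direction) {
    degs_u <- intersect(degs, universe)
    M <- length(degs_u)
    x <- vapply(gene_sets$sets, function(s) length(intersect(s, degs_u)),
                integer(1))
    p <- stats::phyper(x - 1, M, N - M, sizes, lower.tail = FALSE)
    data.frame(pathway = ids, direction = direction, n = unname(sizes),
               x = unname(x), M = M, N = N, p = unname(p),
               z = p_to_z(unname(p), clamp),
               significant = unname(p) < alpha,
               row.names = NULL)
  }

  up <- one_direction(contrast$up, "up")
  down <- one_direction(contrast$down, "down")
  pathways <- rbind(up, down)

  z_comb <- switch(combine,
    max = pmax(up$z, down$z),
    sum = up$z + down$z,
    signed = up$z - down$z)
  combined <- data.frame(pathway = ids,
                         z = z_comb,
                         p_min = pmin(up$p, down$p),
                         significant = pmin(up$p, down$p) < alpha,
                         row.names = NULL)

  structure(list(
    pathways = pathways,
    combined = combined,
    dropped = c(up = length(contrast$up) - length(intersect(contrast$up, universe)),
                down = length(contrast$down) - length(intersect(contrast$down, universe))),
    params = list(alpha = alpha, clamp = clamp, combine = combine),
    metadata = contrast$metadata
  ), class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d pathways, %d significant (p < %g)\n",
              nrow(x$combined), sum(x$combined$significant),
              x$params$alpha))
  invisible(x)
}

#' Meta-z aggregation of pathway z-scores
#'
#' Combines the z-scores of the pathways under a subsystem or system.
#' The default denominator is `sqrt(n)` (Stouffer's method); `n` gives a
#' plain average. A single-element input returns that z under either
#' convention.
#'
#' @param z Numeric vector of pathway z-scores (nonempty).
#' @param denominator `"sqrt_n"` (default) or `"n"`.
#' @return The meta-z-score.
#' @export
meta_z <- function(z, denominator = c("sqrt_n", "n")) {
  denominator <- match.arg(denominator)
  if (!length(z)) stop("meta_z: empty z-score list", call. = FALSE)
  s <- sum(z)
  if (denominator == "sqrt_n") s / sqrt(length(z)) else s / length(z)
}

#' Aggregate pathway scores to subsystem and system meta-z
#'
#' Rolls the per-pathway combined z-scores of an enrichment result up the
#' hierarchy: each subsystem's meta-z combines its member pathways, each
#' system's meta-z combines all pathways under it.
#'
#' @param enrichment An `EnrichmentResult`.
#' @param hierarchy An `AnnotationHierarchy` resolving every scored
#'   pathway.
#' @param denominator Meta-z convention, see [meta_z()].
#' @return An `EnrichmentProfile`: `$subsystems` and `$systems` data
#'   frames (id, meta_z, n_pathways) plus the pathway-level combined table.
#' @export
aggregate_profile <- function(enrichment, hierarchy,
                              denominator = c("sqrt_n", "n")) {
  stopifnot(inherits(enrichment, "EnrichmentResult"),
            inherits(hierarchy, "AnnotationHierarchy"))
  denominator <- match.arg(denominator)
  comb <- enrichment$combined
  if (!nrow(comb)) stop("no pathway scores to aggregate", call. = FALSE)
  missing <- setdiff(comb$pathway, names(hierarchy$pathway_parent))
  if (length(missing)) {
    stop("pathway(s) missing from hierarchy: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub_of <- hierarchy$pathway_parent[comb$pathway]
  sys_of <- hierarchy$subsystem_parent[sub_of]

  roll <- function(keys) {
    groups <- split(comb$z, keys)
    data.frame(id = names(groups),
               meta_z = vapply(groups, meta_z, 0, denominator = denominator),
               n_pathways = lengths(groups),
               row.names = NULL)
  }
  structure(list(subsystems = roll(unname(sub_of)),
                 systems = roll(unname(sys_of)),
                 pathways = comb,
                 denominator = denominator,
                 metadata = enrichment$metadata),
            class = "EnrichmentProfile")
}

#' @export
print.EnrichmentProfile <- function(x, ...) {
  cat(sprintf("EnrichmentProfile: %d pathways -> %d subsystems -> %d systems (meta-z / %s)\n",
              nrow(x$pathways), nrow(x$subsystems), nrow(x$systems),
              x$denominator))
  invisible(x)
}

#' Serialize an EnrichmentProfile to TSV
#'
#' One row per unit: level in {pathway, subsystem, system}, id, score
#' (combined z or meta-z), and the number of contributing pathways.
#'
#' @param profile An `EnrichmentProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "EnrichmentProfile"))
  df <- rbind(
    data.frame(level = "pathway", id = profile$pathways$pathway,
               score = profile$pathways$z, n_pathways = 1L),
    data.frame(level = "subsystem", id = profile$subsystems$id,
               score = profile$subsystems$meta_z,
               n_pathways = profile$subsystems$n_pathways),
    data.frame(level = "system", id = profile$systems$id,
               score = profile$systems$meta_z,
               n_pathways = profile$systems$n_pathways))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
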