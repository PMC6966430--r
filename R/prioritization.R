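# Gene prioritization: S_N, S_FC, per-gene system/subsystem z averages,
# MCS and ARCS, ranking and precision-at-k benchmarking.

minmax <- function(x, lo, hi) {
  if (hi <= lo) return(rep(0, length(x)))  # degenerate pool maps to 0
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Normalized pathway-membership score S_N
#'
#' Min-max normalization of a gene's pathway count against the extreme
#' counts observed over the annotated gene universe.
#'
#' @param n_pathways Pathway count(s) of the gene(s), nonnegative.
#' @param ctx A `NormalizationContext` from
#'   [build_normalization_context()].
#' @return Score(s) in \[0, 1\]; 0 when the pool is degenerate
#'   (max = min).
#' @export
s_n <- function(n_pathways, ctx) {
  stopifnot(inherits(ctx, "NormalizationContext"))
  if (any(n_pathways < 0)) {
    stop("domain error: pathway count must be nonnegative", call. = FALSE)
  }
  minmax(n_pathways, ctx$min_ng, ctx$max_ng)
}

#' Normalized fold-change score S_FC
#'
#' Min-max normalization of a gene's absolute log2 fold change against the
#' extremes over the annotated universe.
#'
#' @param abs_log2fc Absolute log2 fold change(s), nonnegative.
#' @param ctx A `NormalizationContext`.
#' @return Score(s) in \[0, 1\].
#' @export
s_fc <- function(abs_log2fc, ctx) {
  stopifnot(inherits(ctx, "NormalizationContext"))
  if (any(abs_log2fc < 0)) {
    stop("domain error: s_fc expects absolute log2 fold changes",
         call. = FALSE)
  }
  minmax(abs_log2fc, ctx$min_fc, ctx$max_fc)
}

#' Per-gene system- and subsystem-level z averages
#'
#' For every annotated gene, the arithmetic mean of the combined z-scores
#' of its pathways, grouped by the system (and subsystem) those pathways
#' belong to. A gene touching two systems gets one value per system.
#'
#' @param gene_sets A `PathwayGeneSets`.
#' @param hierarchy An `AnnotationHierarchy`.
#' @param z_path Named numeric vector: combined z per pathway (e.g.
#'   `setNames(enr$combined$z, enr$combined$pathway)`).
#' @param genes Optional subset of genes to compute for; defaults to the
#'   whole annotated universe.
#' @return List of two data frames, `zsys` (gene, system, z_mean,
#'   n_pathways) and `zsub` (gene, subsystem, z_mean, n_pathways).
#' @export
gene_level_zsys_zsub <- function(gene_sets, hierarchy, z_path,
                                 genes = NULL) {
  stopifnot(inherits(gene_sets, "PathwayGeneSets"),
            inherits(hierarchy, "AnnotationHierarchy"))
  if (is.null(genes)) genes <- gene_sets$universe
  # long table: (gene, pathway)
  pw <- names(gene_sets$sets)
  long <- data.frame(
    gene = unlist(gene_sets$sets, use.names = FALSE),
    pathway = rep(pw, lengths(gene_sets$sets)))
  long <- long[long$gene %in% genes & long$pathway %in% names(z_path), ]
  long$z <- unname(z_path[long$pathway])
  long$subsystem <- pathway_subsystem(hierarchy, long$pathway)
  long$system <- pathway_system(hierarchy, long$pathway)

  roll <- function(level) {
    key <- paste(long$gene, long[[level]], sep = "\r")
    groups <- split(long$z, key)
    parts <- strsplit(names(groups), "\r", fixed = TRUE)
    out <- data.frame(
      gene = vapply(parts, `[[`, "", 1L),
      level = vapply(parts, `[[`, "", 2L),
      z_mean = vapply(groups, mean, 0),
      n_pathways = lengths(groups),
      row.names = NULL)
    names(out)[2] <- level
    out
  }
  list(zsys = roll("system"), zsub = roll("subsystem"))
}

#' Build the min-max normalization context for gene scoring
#'
#' Pools, over the annotated and measured gene universe: pathway-membership
#' counts (for S_N), absolute log2 fold changes (for S_FC), the raw
#' per-pathway combined z-scores, and the per-gene Zsys / Zsub values.
#' Each pool contributes one global min and max; every scoring term is
#' later min-max normalized against its pool, so all five MCS terms lie in
#' \[0, 1\] for every gene.
#'
#' @param gene_sets A `PathwayGeneSets`.
#' @param hierarchy An `AnnotationHierarchy`.
#' @param z_path Named combined-z vector per pathway.
#' @param abs_log2fc Named vector of absolute log2 fold changes; only
#'   genes present here and in the annotation are pooled.
#' @return A `NormalizationContext`, also carrying the pooled `zsys` /
#'   `zsub` tables for reuse.
#' @export
build_normalization_context <- function(gene_sets, hierarchy, z_path,
                                        abs_log2fc) {
  stopifnot(inherits(gene_sets, "PathwayGeneSets"))
  genes <- intersect(gene_sets$universe, names(abs_log2fc))
  if (!length(genes)) {
    stop("empty universe: no genes are both annotated and measured",
         call. = FALSE)
  }
  counts <- pathway_counts(gene_sets)[genes]
  zz <- gene_level_zsys_zsub(gene_sets, hierarchy, z_path, genes = genes)
  structure(list(
    genes = genes,
    min_ng = min(counts), max_ng = max(counts),
    min_fc = min(abs_log2fc[genes]), max_fc = max(abs_log2fc[genes]),
    min_zpath = min(z_path), max_zpath = max(z_path),
    min_zsys = min(zz$zsys$z_mean), max_zsys = max(zz$zsys$z_mean),
    min_zsub = min(zz$zsub$z_mean), max_zsub = max(zz$zsub$z_mean),
    zsys = zz$zsys, zsub = zz$zsub
  ), class = "NormalizationContext")
}

#' Maximum combined score from per-pathway terms
#'
#' `MCS = max_j(normZsys_j + normZsub_j + normZpath_j) + S_N + S_FC` over
#' the gene's pathways j. With all five terms min-max normalized to
#' \[0, 1\], MCS ranges from 0 to 5.
#'
#' @param pathway_terms Numeric vector: for each of the gene's pathways,
#'   the sum of its three normalized z terms (each in \[0, 1\]).
#' @param s_n,s_fc The gene's normalized S_N and S_FC scores.
#' @return The MCS value.
#' @export
mcs <- function(pathway_terms, s_n, s_fc) {
  if (!length(pathway_terms)) {
    stop("mcs: gene has no annotated pathways", call. = FALSE)
  }
  max(pathway_terms) + s_n + s_fc
}

#' Average root combined score from per-pathway terms
#'
#' `ARCS = (sum_j terms_j + N_i * S_N + S_FC) / sqrt(N_i)` with `N_i` the
#' gene's pathway count (denominator `N_i` available as an option). Unlike
#' MCS its range grows with `N_i`.
#'
#' @inheritParams mcs
#' @param denominator `"sqrt_n"` (default) or `"n"`.
#' @return The ARCS value.
#' @export
arcs <- function(pathway_terms, s_n, s_fc,
                 denominator = c("sqrt_n", "n")) {
  denominator <- match.arg(denominator)
  n_i <- length(pathway_terms)
  if (!n_i) stop("arcs: gene has no annotated pathways", call. = FALSE)
  num <- sum(pathway_terms) + n_i * s_n + s_fc
  if (denominator == "sqrt_n") num / sqrt(n_i) else num / n_i
}

#' Score all genes of a contrast: S_N, S_FC, MCS, ARCS
#'
#' End-to-end gene prioritization for one contrast: builds the
#' normalization context over the annotated, measured universe, computes
#' the per-gene per-pathway normalized term triples, and returns MCS and
#' ARCS with ranks under MCS, ARCS, and absolute fold change. Genes with
#' no annotated pathway receive no MCS/ARCS record.
#'
#' @param contrast A `ContrastResult` (its log2fc supplies S_FC).
#' @param enrichment An `EnrichmentResult` for the same contrast.
#' @param gene_sets A `PathwayGeneSets`.
#' @param hierarchy An `AnnotationHierarchy`.
#' @param arcs_denominator Passed to [arcs()].
#' @return A `GeneScoreTable` data frame: gene, n_pathways, s_n, s_fc,
#'   mcs, arcs, abs_log2fc, rank_mcs, rank_arcs, rank_fc.
#' @export
score_genes <- function(contrast, enrichment, gene_sets, hierarchy,
                        arcs_denominator = c("sqrt_n", "n")) {
  stopifnot(inherits(contrast, "ContrastResult"),
            inherits(enrichment, "EnrichmentResult"))
  arcs_denominator <- match.arg(arcs_denominator)
  z_path <- stats::setNames(enrichment$combined$z,
                            enrichment$combined$pathway)
  abs_fc <- abs(contrast$log2fc)
  ctx <- build_normalization_context(gene_sets, hierarchy, z_path, abs_fc)
  genes <- ctx$genes

  norm_zsys <- stats::setNames(
    minmax(ctx$zsys$z_mean, ctx$min_zsys, ctx$max_zsys),
    paste(ctx$zsys$gene, ctx$zsys$system, sep = "\r"))
  norm_zsub <- stats::setNames(
    minmax(ctx$zsub$z_mean, ctx$min_zsub, ctx$max_zsub),
    paste(ctx$zsub$gene, ctx$zsub$subsystem, sep = "\r"))
  norm_zpath <- stats::setNames(
    minmax(unname(z_path), ctx$min_zpath, ctx$max_zpath), names(z_path))

  # long (gene, pathway) table restricted to scored genes
  pw <- names(gene_sets$sets)
  long <- data.frame(
    gene = unlist(gene_sets$sets, use.names = FALSE),
    pathway = rep(pw, lengths(gene_sets$sets)))
  long <- long[long$gene %in% genes & long$pathway %in% names(z_path), ]
  long$subsystem <- pathway_subsystem(hierarchy, long$pathway)
  long$system <- pathway_system(hierarchy, long$pathway)
  long$term <- norm_zsys[paste(long$gene, long$system, sep = "\r")] +
    norm_zsub[paste(long$gene, long$subsystem, sep = "\r")] +
    norm_zpath[long$pathway]

  terms_by_gene <- split(long$term, long$gene)
  gene_ids <- names(terms_by_gene)
  n_i <- lengths(terms_by_gene)
  sn_v <- s_n(pathway_counts(gene_sets)[gene_ids], ctx)
  sfc_v <- s_fc(abs_fc[gene_ids], ctx)
  mcs_v <- vapply(seq_along(gene_ids), function(i) {
    mcs(terms_by_gene[[i]], sn_v[i], sfc_v[i])
  }, 0)
  arcs_v <- vapply(seq_along(gene_ids), function(i) {
    arcs(terms_by_gene[[i]], sn_v[i], sfc_v[i],
         denominator = arcs_denominator)
  }, 0)

  out <- data.frame(gene = gene_ids, n_pathways = unname(n_i),
                    s_n = unname(sn_v), s_fc = unname(sfc_v),
                    mcs = mcs_v, arcs = arcs_v,
                    abs_log2fc = unname(abs_fc[gene_ids]),
                    row.names = NULL)
  rank_of <- function(score) {
    ord <- order(-score, out$gene, method = "radix")
    r <- integer(length(score)); r[ord] <- seq_along(ord); r
  }
  out$rank_mcs <- rank_of(out$mcs)
  out$rank_arcs <- rank_of(out$arcs)
  out$rank_fc <- rank_of(out$abs_log2fc)
  class(out) <- c("GeneScoreTable", "data.frame")
  attr(out, "context") <- ctx
  out
}

#' Rank genes by a scoring method
#'
#' Descending by score; ties broken deterministically by lexicographic
#' gene id. `"FC"` ranks by absolute log2 fold change and keeps
#' unannotated genes if present in the table; MCS/ARCS rankings contain
#' only genes with at least one annotated pathway.
#'
#' @param scores A `GeneScoreTable` (or data frame with the same columns).
#' @param method `"MCS"`, `"ARCS"`, or `"FC"`.
#' @return Character vector of gene ids, best first.
#' @export
rank_genes <- function(scores, method = c("MCS", "ARCS", "FC")) {
  method <- match.arg(method)
  if (!nrow(scores)) stop("rank_genes: empty score table", call. = FALSE)
  col <- switch(method, MCS = "mcs", ARCS = "arcs", FC = "abs_log2fc")
  keep <- !is.na(scores[[col]])
  s <- scores[keep, ]
  s$gene[order(-s[[col]], s$gene, method = "radix")]
}

#' Precision of the top-k ranked genes against a gold standard
#'
#' `precision = TP / (TP + FP)`: the fraction of the k best-ranked genes
#' present in the positive set.
#'
#' @param ranked Character vector of gene ids, best first.
#' @param gold Character vector of positive gene ids (nonempty).
#' @param k Cutoff, `1 <= k <= length(ranked)`.
#' @return Precision in \[0, 1\].
#' @export
precision_at_k <- function(ranked, gold, k) {
  if (!length(gold)) stop("gold standard is empty", call. = FALSE)
  if (k < 1 || k > length(ranked)) {
    stop("k must lie in [1, length(ranked)]", call. = FALSE)
  }
  mean(ranked[seq_len(k)] %in% gold)
}

#' Precision curve over k = 1..k_max
#'
#' @inheritParams precision_at_k
#' @param k_max Largest cutoff, default the full list.
#' @return Data frame (k, precision).
#' @export
precision_curve <- function(ranked, gold, k_max = length(ranked)) {
  hits <- cumsum(ranked[seq_len(k_max)] %in% gold)
  data.frame(k = seq_len(k_max), precision = hits / seq_len(k_max))
}
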