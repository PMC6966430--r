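#' Construct an ExpressionMatrix
#'
#' Container for a gene-by-sample expression matrix plus the sample sheet.
#' Microarray-like data arrive on the log2 scale (RMA-style intensities);
#' RNA-seq-like data arrive as linear FPKM values, which must be
#' nonnegative.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `genotype`, `diet`;
#'   one row per column of `values`.
#' @param value_scale `"log2"` or `"linear"`.
#' @param platform Free-text platform tag, e.g. `"microarray"` or
#'   `"rnaseq"`.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples,
                              value_scale = c("log2", "linear"),
                              platform = "unspecified") {
  value_scale <- match.arg(value_scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression format error: non-numeric values", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression format error: gene and sample ids required", call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("expression validation error: duplicate gene id ", dup[1],
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("expression validation error: duplicate sample ids", call. = FALSE)
  }
  if (value_scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("expression validation error: negative values on linear scale",
         call. = FALSE)
  }
  required <- c("sample_id", "genotype", "diet")
  if (!all(required %in% names(samples))) {
    stop("sample sheet error: need columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  samples <- as.data.frame(samples)[required]
  unlabeled <- setdiff(colnames(values), samples$sample_id)
  if (length(unlabeled)) {
    stop("sample sheet error: unlabeled sample(s) ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (anyNA(samples$genotype) || anyNA(samples$diet)) {
    stop("sample sheet error: every sample needs a (genotype, diet) label",
         call. = FALSE)
  }
  structure(list(values = values, samples = samples,
                 value_scale = value_scale, platform = platform),
            class = "ExpressionMatrix")
}

#' Load an expression matrix from TSV
#'
#' @param path TSV: first column gene id, remaining columns one per sample.
#' @param sample_sheet Path to a sample-sheet TSV (`sample_id`, `genotype`,
#'   `diet`) or an equivalent data frame.
#' @inheritParams expression_matrix
#' @return An `ExpressionMatrix`.
#' @export
load_expression <- function(path, sample_sheet,
                            value_scale = c("log2", "linear"),
                            platform = "unspecified") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("expression format error: need a gene id column and >=1 sample",
         call. = FALSE)
  }
  genes <- as.character(df[[1]])
  vals <- df[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("expression format error: non-numeric cell at row %d, column '%s'",
                   bad, names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  samples <- if (is.character(sample_sheet)) {
    utils::read.delim(sample_sheet, sep = "\t", colClasses = "character")
  } else sample_sheet
  expression_matrix(m, samples, value_scale = value_scale,
                    platform = platform)
}

#' Group labels of an ExpressionMatrix
#'
#' @param expr An `ExpressionMatrix`.
#' @return Character vector `genotype__diet` per sample (column order).
#' @export
sample_groups <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  paste(expr$samples$genotype, expr$samples$diet, sep = "__")
}

#' Per-gene log2 fold change between two groups
#'
#' Group summaries are arithmetic means of replicate samples on the
#' declared scale. On the log2 scale the fold change is the difference of
#' group means; on the linear scale it is
#' `log2((mean_trt + pseudocount) / (mean_ctl + pseudocount))`.
#'
#' @param expr An `ExpressionMatrix`.
#' @param treatment,control Group labels (`genotype__diet`, see
#'   [sample_groups()]).
#' @param pseudocount Nonnegative stabilizer for linear-scale data.
#'   `NULL` picks the scale default: 1 for linear, 0 for log2.
#' @return Named numeric vector of log2 fold changes.
#' @export
compute_log2fc <- function(expr, treatment, control, pseudocount = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  groups <- sample_groups(expr)
  trt <- expr$values[, groups == treatment, drop = FALSE]
  ctl <- expr$values[, groups == control, drop = FALSE]
  if (ncol(trt) == 0L) stop("empty treatment group: ", treatment, call. = FALSE)
  if (ncol(ctl) == 0L) stop("empty control group: ", control, call. = FALSE)
  if (is.null(pseudocount)) {
    pseudocount <- if (expr$value_scale == "linear") 1 else 0
  }
  if (pseudocount < 0) stop("pseudocount must be nonnegative", call. = FALSE)
  m_trt <- rowMeans(trt)
  m_ctl <- rowMeans(ctl)
  if (expr$value_scale == "log2") {
    m_trt - m_ctl
  } else {
    if (pseudocount == 0 && any(m_trt == 0 | m_ctl == 0)) {
      stop("zero group mean on linear scale; supply a positive pseudocount",
           call. = FALSE)
    }
    log2((m_trt + pseudocount) / (m_ctl + pseudocount))
  }
}

#' Select up/down DEG sets by fold-change threshold
#'
#' A gene is an up-DEG when its log2 fold change meets `log2(threshold)`
#' and a down-DEG when it meets `-log2(threshold)`; with the default
#' inclusive comparator a gene exactly at the threshold is included
#' (fold change >= 2).
#'
#' @param log2fc Named numeric vector of per-gene log2 fold changes.
#' @param threshold Fold-change threshold on the linear scale, >= 1.
#' @param comparator `">="` (default) or `">"`.
#' @param metadata Optional named list carried along (platform, genotype,
#'   diet pair, ...).
#' @return A `ContrastResult`: log2fc, disjoint `up`/`down` gene sets,
#'   threshold, comparator, metadata.
#' @export
select_degs <- function(log2fc, threshold = 2, comparator = c(">=", ">"),
                        metadata = list()) {
  comparator <- match.arg(comparator)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1) {
    stop("parameter error: fold-change threshold must be >= 1", call. = FALSE)
  }
  if (is.null(names(log2fc))) {
    stop("log2fc must be a named vector", call. = FALSE)
  }
  cut <- log2(threshold)
  cmp <- if (comparator == ">=") `>=` else `>`
  up <- names(log2fc)[cmp(log2fc, cut)]
  down <- names(log2fc)[cmp(-log2fc, cut)]
  if (threshold == 1 && comparator == ">=") {
    # degenerate threshold: a gene at log2fc exactly 0 satisfies both sides;
    # keep the sets disjoint by excluding it from both
    both <- intersect(up, down)
    up <- setdiff(up, both)
    down <- setdiff(down, both)
  }
  structure(list(log2fc = log2fc, up = up, down = down,
                 threshold = threshold, comparator = comparator,
                 metadata = metadata),
            class = "ContrastResult")
}

#' @export
print.ContrastResult <- function(x, ...) {
  cat(sprintf("ContrastResult: %d genes, %d up / %d down at fold change %s %g\n",
              length(x$log2fc), length(x$up), length(x$down),
              x$comparator, x$threshold))
  invisible(x)
}

#' Serialize a ContrastResult to TSV
#'
#' Columns: gene, log2fc, call in {up, down, ns}.
#'
#' @param contrast A `ContrastResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path) {
  stopifnot(inherits(contrast, "ContrastResult"))
  call <- rep("ns", length(contrast$log2fc))
  call[names(contrast$log2fc) %in% contrast$up] <- "up"
  call[names(contrast$log2fc) %in% contrast$down] <- "down"
  utils::write.table(
    data.frame(gene = names(contrast$log2fc),
               log2fc = unname(contrast$log2fc), call = call),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
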