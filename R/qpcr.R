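# Efficiency-adjusted comparative-Ct (delta-delta-Ct) relative expression.

#' Efficiency-adjusted ddCt fold change
#'
#' `ddCt = (Ct_target,exp - Ct_ref,exp) - (Ct_target,ctl - Ct_ref,ctl)`
#' and fold change = `base^(-ddCt)`. The default base 1.94 is the
#' amplification-efficiency factor used for the qPCR validation (a
#' perfectly efficient reaction would double per cycle, base 2).
#'
#' @param ct_target_exp,ct_ref_exp Target and reference-gene Ct in the
#'   experimental group.
#' @param ct_target_ctl,ct_ref_ctl Target and reference-gene Ct in the
#'   control group.
#' @param base Amplification efficiency factor, > 1; default 1.94.
#' @return The relative-expression fold change.
#' @export
ddct_fold_change <- function(ct_target_exp, ct_ref_exp,
                             ct_target_ctl, ct_ref_ctl, base = 1.94) {
  if (!is.numeric(base) || length(base) != 1L || base <= 1) {
    stop("parameter error: efficiency base must be > 1", call. = FALSE)
  }
  cts <- c(ct_target_exp, ct_ref_exp, ct_target_ctl, ct_ref_ctl)
  if (any(!is.finite(cts))) {
    stop("all Ct values must be finite", call. = FALSE)
  }
  ddct <- (ct_target_exp - ct_ref_exp) - (ct_target_ctl - ct_ref_ctl)
  base^(-ddct)
}

#' Median and standard error of a group of fold changes
#'
#' Groups are summarized as median plus standard error
#' (sample sd / sqrt(n)); at least 3 independent samples are required.
#'
#' @param fold_changes Numeric vector, length >= 3.
#' @return List with `median`, `se`, `n`.
#' @export
summarize_group <- function(fold_changes) {
  n <- length(fold_changes)
  if (n < 3L) {
    stop("summarize_group: at least 3 independent samples required",
         call. = FALSE)
  }
  list(median = stats::median(fold_changes),
       se = stats::sd(fold_changes) / sqrt(n),
       n = n)
}

#' Load a Ct table from CSV
#'
#' @param path CSV with columns `sample`, `group`, `gene`, `ct`.
#' @return Data frame with those columns; Ct values must be positive and
#'   finite.
#' @export
load_ct_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(sample = "character",
                                             group = "character",
                                             gene = "character"))
  required <- c("sample", "group", "gene", "ct")
  if (!all(required %in% names(df))) {
    stop("Ct table format error: need columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("Ct table validation error: Ct values must be positive and finite",
         call. = FALSE)
  }
  df[required]
}

#' Relative expression of target genes from a Ct table
#'
#' Technical-replicate Cts are averaged per (sample, gene) first;
#' biological samples stay separate. Each experimental sample's ddCt is
#' taken against the mean delta-Ct of the control group, converted to a
#' fold change with [ddct_fold_change()]'s efficiency base, and the
#' per-group fold changes are summarized as median and standard error.
#'
#' @param ct_table Data frame as returned by [load_ct_table()].
#' @param reference_gene Internal-control gene id (actin-style).
#' @param control_group Group label serving as calibrator.
#' @param base Amplification efficiency factor, default 1.94.
#' @return Data frame: gene, group, median_fc, se, n.
#' @export
relative_expression <- function(ct_table, reference_gene, control_group,
                                base = 1.94) {
  if (!reference_gene %in% ct_table$gene) {
    stop("reference gene ", reference_gene, " absent from Ct table",
         call. = FALSE)
  }
  if (!control_group %in% ct_table$group) {
    stop("control group ", control_group, " absent from Ct table",
         call. = FALSE)
  }
  # collapse technical replicates
  agg <- stats::aggregate(ct ~ sample + group + gene, data = ct_table,
                          FUN = mean)
  ref <- agg[agg$gene == reference_gene,
             c("sample", "group", "ct")]
  names(ref)[3] <- "ct_ref"
  missing_ref <- setdiff(unique(agg$sample), ref$sample)
  if (length(missing_ref)) {
    stop("reference gene missing for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  targets <- agg[agg$gene != reference_gene, ]
  targets <- merge(targets, ref[c("sample", "ct_ref")], by = "sample")
  targets$dct <- targets$ct - targets$ct_ref

  out <- list()
  for (g in unique(targets$gene)) {
    tg <- targets[targets$gene == g, ]
    ctl_dct <- tg$dct[tg$group == control_group]
    if (!length(ctl_dct)) {
      stop("no control-group measurements for gene ", g, call. = FALSE)
    }
    calibrator <- mean(ctl_dct)
    for (grp in unique(tg$group)) {
      fc <- base^(-(tg$dct[tg$group == grp] - calibrator))
      s <- summarize_group(fc)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, group = grp, median_fc = s$median, se = s$se, n = s$n)
    }
  }
  do.call(rbind, out)
}
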