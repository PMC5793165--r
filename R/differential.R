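#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard FDR step-up transform; input order is preserved and every
#' adjusted value lies in \[0, 1\].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted values (q-values) in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!is.numeric(pvalues)) stop_input("pvalues must be numeric")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_input("pvalues must be finite and in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Differential expression between tumor and normal samples
#'
#' Genes whose median normalised expression across all samples is below
#' `min_median` are flagged `filtered_low_expression` and excluded from
#' testing and multiple-testing correction. Remaining genes are tested by
#' Welch's two-sample t on `log2(x + 1)`, BH-adjusted, and labelled
#' `up` / `down` / `ns` by `|log2fc| > lfc_cut` and `qvalue < fdr_cut`.
#' The fold change is `log2((mean_tumor + eps) / (mean_normal + eps))` on
#' the normalised scale with pseudocount `eps`.
#'
#' @param expr non-negative gene x sample matrix of normalised expression
#'   (e.g. FPKM or counts-per-million).
#' @param conditions character vector (`"normal"` / `"tumor"`), named by
#'   sample or aligned with the columns; >= 2 samples per condition.
#' @param min_median inclusive expression floor: genes with median
#'   expression >= `min_median` are tested.
#' @param lfc_cut absolute log2 fold-change threshold (exclusive).
#' @param fdr_cut FDR threshold (exclusive).
#' @param pseudocount fold-change pseudocount.
#' @return data frame with one row per gene: `gene_id`, `mean_normal`,
#'   `mean_tumor`, `log2fc`, `pvalue`, `qvalue`, `status`.
#' @export
differential_expression <- function(expr, conditions, min_median = 0.5,
                                    lfc_cut = 0.5, fdr_cut = 0.05,
                                    pseudocount = 0.25) {
  if (any(expr < 0)) stop_input("expression values must be non-negative")
  if (anyDuplicated(rownames(expr)))
    stop_input("gene ids (rownames) must be unique")
  conditions <- check_conditions(conditions, colnames(expr))
  genes <- rownames(expr)
  med <- apply(expr, 1, median)
  tested <- med >= min_median

  nx <- expr[, conditions == "normal", drop = FALSE]
  tx <- expr[, conditions == "tumor", drop = FALSE]
  mean_normal <- rowMeans(nx)
  mean_tumor <- rowMeans(tx)
  log2fc <- log2((mean_tumor + pseudocount) / (mean_normal + pseudocount))

  pvalue <- rep(NA_real_, length(genes))
  qvalue <- rep(NA_real_, length(genes))
  if (any(tested)) {
    wt <- row_welch(log2(nx[tested, , drop = FALSE] + 1),
                    log2(tx[tested, , drop = FALSE] + 1))
    pvalue[tested] <- wt$pvalue
    qvalue[tested] <- benjamini_hochberg(wt$pvalue)
  }
  status <- rep("ns", length(genes))
  status[!tested] <- "filtered_low_expression"
  sig <- tested & abs(log2fc) > lfc_cut & qvalue < fdr_cut
  sig[is.na(sig)] <- FALSE
  status[sig & log2fc > 0] <- "up"
  status[sig & log2fc < 0] <- "down"
  data.frame(gene_id = genes, mean_normal = mean_normal,
             mean_tumor = mean_tumor, log2fc = log2fc, pvalue = pvalue,
             qvalue = qvalue, status = status, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential promoter methylation between tumor and normal samples
#'
#' Welch's two-sample t on the per-gene promoter beta values,
#' BH-adjusted. A gene is significant only if its q-value passes both
#' configured criteria (`qvalue <= q_cut` and `qvalue < fdr_cut`);
#' significant genes are labelled `hyper` or `hypo` by the sign of
#' `delta_beta = mean_beta_tumor - mean_beta_normal`. Genes with zero
#' variance in both groups get p = 0 when the group means differ and
#' p = 1 when they are equal.
#'
#' @param beta gene x sample matrix with entries in \[0, 1\].
#' @param conditions as in [differential_expression()].
#' @param q_cut inclusive q-value ceiling.
#' @param fdr_cut exclusive FDR threshold.
#' @return data frame: `gene_id`, `mean_beta_normal`, `mean_beta_tumor`,
#'   `delta_beta`, `statistic`, `pvalue`, `qvalue`, `direction`.
#' @export
differential_methylation <- function(beta, conditions, q_cut = 0.0075,
                                     fdr_cut = 0.05) {
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("beta outside [0, 1] for gene %s, sample %s",
               rownames(beta)[bad[1, 1]] %||% bad[1, 1],
               colnames(beta)[bad[1, 2]] %||% bad[1, 2])
  conditions <- check_conditions(conditions, colnames(beta))
  nx <- beta[, conditions == "normal", drop = FALSE]
  tx <- beta[, conditions == "tumor", drop = FALSE]
  wt <- row_welch(nx, tx)
  qvalue <- benjamini_hochberg(wt$pvalue)
  delta <- wt$mean2 - wt$mean1
  sig <- qvalue <= q_cut & qvalue < fdr_cut
  direction <- rep("ns", nrow(beta))
  direction[sig & delta > 0] <- "hyper"
  direction[sig & delta < 0] <- "hypo"
  data.frame(gene_id = rownames(beta), mean_beta_normal = wt$mean1,
             mean_beta_tumor = wt$mean2, delta_beta = delta,
             statistic = wt$statistic, pvalue = wt$pvalue, qvalue = qvalue,
             direction = direction, row.names = NULL, stringsAsFactors = FALSE)
}
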