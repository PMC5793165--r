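#' Target enrichment of a TF in a regulatory network
#'
#' Builds the 2x2 table over the gene universe -- `a` targets inside the
#' network, `b` targets outside, `c` non-targets inside, `d` non-targets
#' outside -- and computes the sample odds ratio `(a*d)/(b*c)` (with the
#' Haldane-Anscombe 0.5 correction when any cell is zero) and the
#' two-sided Fisher exact p-value by summation of hypergeometric point
#' probabilities no larger than that of the observed table (with the
#' customary `1 + 1e-7` relative tolerance).
#'
#' @param tf TF gene id (bookkeeping only; not removed from the table).
#' @param network_genes genes inside the network.
#' @param targets the TF's target genes (within the universe).
#' @param universe the gene universe for the table.
#' @return one-row data frame: `tf`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `pvalue`.
#' @export
fisher_enrichment <- function(tf, network_genes, targets, universe) {
  if (length(universe) == 0) stop_input("empty gene universe")
  targets <- intersect(targets, universe)
  network_genes <- intersect(network_genes, universe)
  a <- length(intersect(targets, network_genes))
  b <- length(targets) - a
  c_ <- length(network_genes) - a
  d <- length(universe) - a - b - c_
  data.frame(tf = tf, a = a, b = b, c = c_, d = d,
             odds_ratio = odds_ratio_2x2(a, b, c_, d),
             pvalue = fisher_two_sided(a, b, c_, d),
             stringsAsFactors = FALSE)
}

odds_ratio_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

## two-sided Fisher exact p by the point-probability rule
fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # targets
  k <- a + c          # network size
  N <- a + b + c + d
  support <- max(0, k - (N - m)):min(m, k)
  probs <- dhyper(support, m, N - m, k)
  p_obs <- dhyper(a, m, N - m, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Identify key transcription factors across regulatory networks
#'
#' Evaluates every TF of the interaction map against every network with
#' [fisher_enrichment()], BH-adjusts the p-values per network, and
#' classifies TFs by the conjunction of evidence: \describe{
#'   \item{key_tfs_in_network}{present as a node in at least one
#'     network, target enrichment p < `alpha` in at least one network,
#'     and a significant somatic mutation (q < `mut_q`).}
#'   \item{enriched_only_tfs}{enrichment p < `alpha` but no significant
#'     mutation.}
#'   \item{key_tfs_outside}{expression unchanged in tumor (`ns` in the
#'     DEG table), enrichment p < `alpha`, and a significant mutation --
#'     regulators invisible to differential expression.}}
#' Selection uses the raw enrichment p-value; the BH q-values are
#' reported alongside for stricter use. When the mutation table has an
#' `is_driver` column it further restricts the outside list.
#'
#' @param networks named list of `regulatory_network` objects.
#' @param tf_targets interaction map ([read_tf_targets()] schema).
#' @param deg [differential_expression()] table.
#' @param mutations data frame with `gene_id`, `qvalue` (and optionally
#'   `is_driver`).
#' @param universe gene universe for the 2x2 tables; defaults to the
#'   union of module genes underlying the supplied networks.
#' @param alpha enrichment p-value threshold.
#' @param mut_q mutation significance threshold.
#' @return list with `enrichment` (per TF x network table),
#'   `key_tfs_in_network`, `enriched_only_tfs`, `key_tfs_outside`.
#' @export
identify_key_tfs <- function(networks, tf_targets, deg, mutations,
                             universe = NULL, alpha = 0.05, mut_q = 0.05) {
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(networks, `[[`, "module_genes"))))
  ids <- names(networks) %||% vapply(networks, `[[`, "", "module_id")
  tfs <- sort(unique(tf_targets$tf_gene_id))
  rows <- list()
  for (tf in tfs) {
    targets <- intersect(tf_targets$target_gene_id[
      tf_targets$tf_gene_id == tf], universe)
    if (length(targets) == 0) {
      warning(sprintf("TF %s has no targets in the universe; skipped", tf))
      next
    }
    for (i in seq_along(networks)) {
      er <- fisher_enrichment(tf, networks[[i]]$nodes$gene_id, targets,
                              universe)
      er$network <- ids[i]
      er$in_network <- tf %in% networks[[i]]$nodes$gene_id
      rows[[length(rows) + 1]] <- er
    }
  }
  enr <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), odds_ratio = numeric(0),
               pvalue = numeric(0), network = character(0),
               in_network = logical(0))
  enr$qvalue <- NA_real_
  for (id in unique(enr$network)) {
    sel <- enr$network == id
    enr$qvalue[sel] <- benjamini_hochberg(enr$pvalue[sel])
  }
  enr <- enr[, c("tf", "network", "a", "b", "c", "d", "odds_ratio",
                 "pvalue", "qvalue", "in_network")]

  mut_sig <- mutations$gene_id[mutations$qvalue < mut_q]
  driver_ok <- if ("is_driver" %in% names(mutations))
    mutations$gene_id[as.logical(mutations$is_driver)] else NULL
  deg_ns <- deg$gene_id[deg$status == "ns"]

  enriched_any <- unique(enr$tf[enr$pvalue < alpha])
  node_any <- unique(enr$tf[enr$in_network])
  key_in <- sort(intersect(intersect(enriched_any, node_any), mut_sig))
  enriched_only <- sort(setdiff(enriched_any, mut_sig))
  outside <- intersect(intersect(enriched_any, deg_ns), mut_sig)
  if (!is.null(driver_ok)) outside <- intersect(outside, driver_ok)
  list(enrichment = enr,
       key_tfs_in_network = key_in,
       enriched_only_tfs = enriched_only,
       key_tfs_outside = sort(outside))
}

#' Identify key lncRNAs from assembled networks
#'
#' An lncRNA is key when it retains at least one outgoing regulatory
#' edge and at least one of its retained protein-coding targets has a
#' binding score of `min_score` or more. Protein-coding and lncRNA
#' targets are listed separately.
#'
#' @param networks named list of `regulatory_network` objects (binding
#'   filter already applied during assembly).
#' @param binding binding-score table (`lncrna_gene_id`,
#'   `protein_gene_id`, `score`).
#' @param annotation annotation with `gene_id`, `biotype`.
#' @param min_score inclusive binding-score threshold.
#' @return list with `key_lncrnas` (data frame `lncrna`, `network`,
#'   `n_protein_targets`, `n_lncrna_targets`) and `targets` (one row per
#'   retained out-edge of a key lncRNA, with biotype and score).
#' @export
identify_key_lncrnas <- function(networks, binding, annotation,
                                 min_score = 25) {
  biotype <- setNames(annotation$biotype, annotation$gene_id)
  scores <- binding_lookup(binding)
  ids <- names(networks) %||% vapply(networks, `[[`, "", "module_id")
  keys <- list(); tgts <- list()
  for (i in seq_along(networks)) {
    ed <- networks[[i]]$edges
    if (nrow(ed) == 0) next
    lnc_src <- unique(ed$from[biotype[ed$from] == "lncRNA"])
    for (ln in lnc_src) {
      out <- ed[ed$from == ln, , drop = FALSE]
      out$biotype <- unname(biotype[out$to])
      out$score <- unname(scores[paste(ln, out$to, sep = "\r")])
      prot <- out[out$biotype == "protein_coding", , drop = FALSE]
      bound <- !is.na(prot$score) & prot$score >= min_score
      if (!any(bound)) next
      keys[[length(keys) + 1]] <- data.frame(
        lncrna = ln, network = ids[i],
        n_protein_targets = nrow(prot),
        n_lncrna_targets = sum(out$biotype == "lncRNA"),
        stringsAsFactors = FALSE)
      tgts[[length(tgts) + 1]] <- data.frame(
        lncrna = ln, network = ids[i], target = out$to,
        target_biotype = out$biotype, binding_score = out$score,
        stringsAsFactors = FALSE)
    }
  }
  empty_keys <- data.frame(lncrna = character(0), network = character(0),
                           n_protein_targets = integer(0),
                           n_lncrna_targets = integer(0))
  empty_tgts <- data.frame(lncrna = character(0), network = character(0),
                           target = character(0),
                           target_biotype = character(0),
                           binding_score = numeric(0))
  list(key_lncrnas = if (length(keys)) do.call(rbind, keys) else empty_keys,
       targets = if (length(tgts)) do.call(rbind, tgts) else empty_tgts)
}

#' Pairwise expression correlations
#'
#' Pearson correlation for each requested gene pair over a sample
#' subset. Pairs involving a constant expression vector are reported as
#' `NA` and excluded from the median.
#'
#' @param expr gene x sample expression matrix.
#' @param pairs two-column data frame or matrix of gene ids.
#' @param samples sample subset (default: all columns); needs >= 3.
#' @return list with `pairs` (data frame `gene1`, `gene2`, `cor`) and
#'   `median_cor` (median over defined correlations).
#' @export
pair_correlation <- function(expr, pairs, samples = colnames(expr)) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) stop_input("pairs must have two columns")
  if (length(samples) < 3) stop_input("need >= 3 samples for correlations")
  missing <- setdiff(unique(unlist(pairs[, 1:2])), rownames(expr))
  if (length(missing))
    stop_input("gene(s) absent from the expression matrix: %s",
               paste(utils::head(missing, 3), collapse = ", "))
  sub <- expr[, samples, drop = FALSE]
  cc <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- sub[pairs[i, 1], ]; y <- sub[pairs[i, 2], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  out <- data.frame(gene1 = pairs[, 1], gene2 = pairs[, 2], cor = cc,
                    stringsAsFactors = FALSE)
  list(pairs = out, median_cor = median(cc, na.rm = TRUE))
}
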