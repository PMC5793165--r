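#' TF-to-target edges within a module
#'
#' For every (TF, target) interaction whose two genes both belong to the
#' module, emits one directed edge TF -> target with provenance `tf_db`.
#'
#' @param module_genes character vector of module member gene ids.
#' @param tf_targets data frame with columns `tf_gene_id`,
#'   `target_gene_id` (see [read_tf_targets()]).
#' @return data frame `from`, `to`, `provenance`.
#' @export
tf_target_edges <- function(module_genes, tf_targets) {
  hit <- tf_targets$tf_gene_id %in% module_genes &
    tf_targets$target_gene_id %in% module_genes
  data.frame(from = tf_targets$tf_gene_id[hit],
             to = tf_targets$target_gene_id[hit],
             provenance = if (any(hit)) "tf_db" else character(0),
             stringsAsFactors = FALSE)
}

binding_lookup <- function(binding) {
  setNames(binding$score,
           paste(binding$lncrna_gene_id, binding$protein_gene_id, sep = "\r"))
}

#' Filter lncRNA-to-protein edges by binding score
#'
#' Edges whose source is an lncRNA and whose target is protein-coding
#' are kept only when their binding score is at least `min_score`
#' (inclusive: a score of exactly 25 is real binding); a missing score
#' counts as below threshold. Edges between any other biotype pair,
#' including lncRNA -> lncRNA, pass through untouched.
#'
#' @param edges data frame with `from`, `to` columns.
#' @param binding data frame `lncrna_gene_id`, `protein_gene_id`, `score`.
#' @param annotation data frame with `gene_id` and `biotype`.
#' @param min_score inclusive binding-score threshold.
#' @return the filtered edge data frame.
#' @export
lncrna_binding_filter <- function(edges, binding, annotation, min_score = 25) {
  if (nrow(edges) == 0) return(edges)
  biotype <- setNames(annotation$biotype, annotation$gene_id)
  applies <- biotype[edges$from] == "lncRNA" &
    biotype[edges$to] == "protein_coding"
  applies[is.na(applies)] <- FALSE
  score <- binding_lookup(binding)[paste(edges$from, edges$to, sep = "\r")]
  keep <- !applies | (!is.na(score) & score >= min_score)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune regulatory edges explained by promoter methylation
#'
#' Default `categorical` mode removes every edge pointing into a gene
#' that is under-expressed in tumor (`status == "down"`) with a gain of
#' promoter methylation (`direction == "hyper"`): such silencing is
#' attributed to the epigenetic change, not to an upstream regulator.
#' `correlation` mode instead removes edges into targets whose tumor
#' expression is negatively correlated with their promoter beta at
#' `cor <= -corr_cut`.
#'
#' @param edges data frame with `from`, `to` columns.
#' @param deg [differential_expression()] table.
#' @param dm [differential_methylation()] table.
#' @param mode `"categorical"` or `"correlation"`.
#' @param expr,beta matrices over tumor samples (correlation mode only).
#' @param corr_cut threshold for the negative expression-methylation
#'   correlation (correlation mode).
#' @return list with `edges` (kept) and `removed` (with a `reason`
#'   column).
#' @export
methylation_prune <- function(edges, deg, dm, mode = "categorical",
                              expr = NULL, beta = NULL, corr_cut = 0.3) {
  if (!mode %in% c("categorical", "correlation"))
    stop_input("unknown methylation pruning mode '%s'", mode)
  if (nrow(edges) == 0)
    return(list(edges = edges,
                removed = cbind(edges, reason = character(0))))
  if (mode == "categorical") {
    down <- deg$gene_id[deg$status == "down"]
    hyper <- dm$gene_id[dm$direction == "hyper"]
    silenced <- intersect(down, hyper)
    drop <- edges$to %in% silenced
    reason <- rep("target down-regulated with promoter hypermethylation",
                  sum(drop))
  } else {
    if (is.null(expr) || is.null(beta))
      stop_input("correlation mode requires tumor expression and beta matrices")
    targets <- unique(edges$to)
    targets <- targets[targets %in% rownames(expr) &
                         targets %in% rownames(beta)]
    cc <- vapply(targets, function(g) {
      e <- expr[g, ]; b <- beta[g, ]
      if (stats::sd(e) == 0 || stats::sd(b) == 0) return(NA_real_)
      cor(e, b)
    }, numeric(1))
    flagged <- targets[!is.na(cc) & cc <= -corr_cut]
    drop <- edges$to %in% flagged
    reason <- rep("target expression anti-correlated with promoter methylation",
                  sum(drop))
  }
  removed <- edges[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason
  else removed$reason <- character(0)
  kept <- edges[!drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(edges = kept, removed = removed)
}

#' Assemble a module's regulatory network
#'
#' Merges Bayesian edges with TF-target edges (duplicate (from, to)
#' pairs get the union of provenances and keep the bootstrap strength),
#' applies the lncRNA binding-score filter and the methylation prune,
#' then drops genes left without any edge, so every retained node has
#' in-degree + out-degree >= 1. Node and edge order in the result is
#' deterministic.
#'
#' @param module_id module identifier.
#' @param module_genes member gene ids.
#' @param bn_edges data frame from [select_directed_edges()] (may have
#'   zero rows).
#' @param tf_edges data frame from [tf_target_edges()].
#' @param binding,annotation,deg,dm inputs for the two filters.
#' @param min_score,prune_mode,expr,beta,corr_cut filter parameters.
#' @return object of class `regulatory_network`: list with `module_id`,
#'   `nodes` (`gene_id`, `biotype`, `is_tf`), `edges` (`from`, `to`,
#'   `provenance`, `strength`), `removed_edges`, and `n_module_genes`.
#' @export
assemble_network <- function(module_id, module_genes, bn_edges, tf_edges,
                             binding, annotation, deg, dm, min_score = 25,
                             prune_mode = "categorical", expr = NULL,
                             beta = NULL, corr_cut = 0.3) {
  norm_edges <- function(df, prov) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(from = character(0), to = character(0),
                        provenance = character(0), strength = numeric(0),
                        stringsAsFactors = FALSE))
    data.frame(from = df$from, to = df$to, provenance = prov,
               strength = df$strength %||% rep(NA_real_, nrow(df)),
               stringsAsFactors = FALSE)
  }
  all_edges <- rbind(norm_edges(bn_edges, "bayes"),
                     norm_edges(tf_edges, "tf_db"))
  outside <- setdiff(unique(c(all_edges$from, all_edges$to)), module_genes)
  if (length(outside))
    stop_input("edge endpoint outside the module: %s", outside[1])
  self <- all_edges$from == all_edges$to
  all_edges <- all_edges[!self, , drop = FALSE]
  if (nrow(all_edges)) {
    key <- paste(all_edges$from, all_edges$to, sep = "\r")
    merged <- lapply(split(seq_len(nrow(all_edges)), key), function(idx) {
      rows <- all_edges[idx, , drop = FALSE]
      st <- rows$strength[!is.na(rows$strength)]
      data.frame(from = rows$from[1], to = rows$to[1],
                 provenance = paste(sort(unique(rows$provenance)),
                                    collapse = ","),
                 strength = if (length(st)) st[1] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    all_edges <- do.call(rbind, merged)
  }
  all_edges <- lncrna_binding_filter(all_edges, binding, annotation,
                                     min_score)
  pr <- methylation_prune(all_edges, deg, dm, mode = prune_mode,
                          expr = expr, beta = beta, corr_cut = corr_cut)
  edges <- pr$edges
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  in_net <- sort(unique(c(edges$from, edges$to)))
  ann <- annotation[match(in_net, annotation$gene_id), , drop = FALSE]
  nodes <- data.frame(gene_id = in_net,
                      biotype = ann$biotype,
                      is_tf = as.integer(ann$is_tf),
                      stringsAsFactors = FALSE)
  structure(list(module_id = module_id, nodes = nodes, edges = edges,
                 removed_edges = pr$removed, module_genes = module_genes,
                 n_module_genes = length(module_genes)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory network %s: %d nodes, %d edges (%.1f%% of %d module genes retained)\n",
              x$module_id, nrow(x$nodes), nrow(x$edges),
              100 * nrow(x$nodes) / max(1, x$n_module_genes),
              x$n_module_genes))
  invisible(x)
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Write a regulatory network to disk
#'
#' Writes `edges.tsv` (from, to, provenance, strength), a SIF file
#' (`from TAB regulates TAB to`) and GraphML with node attributes
#' `biotype` / `is_tf` and edge attributes `provenance` / `strength`.
#'
#' @param net a `regulatory_network`.
#' @param directory output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(directory, c("edges.tsv", "network.sif",
                                  "network.graphml"))
  write_tsv(net$edges, paths[1])
  sif <- sprintf("%s\tregulates\t%s", net$edges$from, net$edges$to)
  writeLines(sif, paths[2])
  if (nrow(net$nodes)) {
    g <- network_igraph(net)
    igraph::E(g)$strength[is.na(igraph::E(g)$strength)] <- -1
    igraph::write_graph(g, paths[3], format = "graphml")
  } else {
    writeLines("<graphml/>", paths[3])
  }
  invisible(paths)
}
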