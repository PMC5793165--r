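#' Build and validate a pipeline run configuration
#'
#' A flat configuration for [run_pipeline()] and the stage runners.
#' Unknown keys are rejected; thresholds are validated before any
#' computation. Either `simulate` (a list of [synthetic_config()]
#' arguments) or `input_dir` (a directory in the [write_fixture()]
#' schema) must be provided.
#'
#' @param out_dir output directory.
#' @param seed integer seed for every stochastic stage (mandatory).
#' @param simulate list of [synthetic_config()] arguments, or NULL.
#' @param input_dir directory of input TSVs, or NULL when simulating.
#' @param min_median,lfc_cut,fdr_cut differential-expression thresholds.
#' @param dm_q_cut,dm_fdr_cut differential-methylation thresholds.
#' @param power_candidates,r2_target soft-power selection controls.
#' @param fallback_power soft power used when no candidate reaches the
#'   scale-free fit target (block-modular data is not scale-free, so the
#'   fit index is uninformative there; a low power preserves the
#'   module/background contrast the static tree cut relies on).
#' @param min_module_size,cut_height module detection controls.
#' @param bn_bootstrap,bn_restarts,bn_boot_restarts,max_parents,max_bn_genes
#'   structure-learning controls; modules larger than `max_bn_genes` are
#'   refused.
#' @param strength_cut,cor_cut directed-edge retention thresholds.
#' @param min_binding lncRNA binding-score threshold.
#' @param prune_mode methylation pruning mode.
#' @param deletion_fraction,robustness_iterations robustness controls.
#' @param alpha,mut_q key-TF thresholds.
#' @param ... rejected; present so misspelled keys fail loudly.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, simulate = NULL, input_dir = NULL,
                            min_median = 0.5, lfc_cut = 0.5, fdr_cut = 0.05,
                            dm_q_cut = 0.0075, dm_fdr_cut = 0.05,
                            power_candidates = 1:20, r2_target = 0.8,
                            fallback_power = 2,
                            min_module_size = 30, cut_height = 0.85,
                            bn_bootstrap = 100, bn_restarts = 5,
                            bn_boot_restarts = 1, max_parents = 5,
                            max_bn_genes = 500, strength_cut = 0.75,
                            cor_cut = 0.3, min_binding = 25,
                            prune_mode = "categorical",
                            deletion_fraction = 0.02,
                            robustness_iterations = 100,
                            alpha = 0.05, mut_q = 0.05, ...) {
  extra <- list(...)
  if (length(extra))
    stop_input("unknown configuration key(s): %s",
               paste(names(extra), collapse = ", "))
  if (missing(seed)) stop_input("seed is mandatory")
  cfg <- mget(setdiff(names(formals(pipeline_config)), "..."))
  in01 <- function(field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[field]]
    ok <- is.numeric(v) && length(v) == 1 &&
      (v > lo || (!lo_open && v == lo)) && (v < hi || (!hi_open && v == hi))
    if (!ok) stop_input("configuration field '%s' out of range", field)
  }
  in01("fdr_cut"); in01("dm_q_cut"); in01("dm_fdr_cut")
  in01("strength_cut"); in01("cor_cut"); in01("alpha"); in01("mut_q")
  in01("deletion_fraction", hi_open = TRUE)
  in01("r2_target")
  if (min_median < 0) stop_input("configuration field 'min_median' out of range")
  if (lfc_cut < 0) stop_input("configuration field 'lfc_cut' out of range")
  if (min_binding < 0 || min_binding > 100)
    stop_input("configuration field 'min_binding' out of range")
  if (min_module_size < 2)
    stop_input("configuration field 'min_module_size' out of range")
  for (f in c("bn_bootstrap", "bn_restarts", "bn_boot_restarts",
              "max_parents", "max_bn_genes", "robustness_iterations"))
    if (cfg[[f]] < 1) stop_input("configuration field '%s' out of range", f)
  if (!prune_mode %in% c("categorical", "correlation"))
    stop_input("configuration field 'prune_mode' must be categorical or correlation")
  if (is.null(simulate) && is.null(input_dir))
    stop_input("either 'simulate' or 'input_dir' must be given")
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...)))
}

in_dir <- function(config) config$input_dir %||% file.path(config$out_dir, "input")
in_path <- function(config, file) file.path(in_dir(config), file)
out_path <- function(config, ...) file.path(config$out_dir, ...)

read_conditions <- function(config) {
  smp <- read_tsv_checked(in_path(config, "samples.tsv"),
                          c("sample_id", "condition"))
  setNames(smp$condition, smp$sample_id)
}

## log2(normalised + 1) restricted to given genes and tumor samples;
## the substrate for co-expression and structure learning
tumor_log_expr <- function(config, genes = NULL) {
  norm <- read_matrix_tsv(in_path(config, "expression_norm.tsv"))
  conditions <- read_conditions(config)
  tum <- names(conditions)[conditions == "tumor"]
  if (!is.null(genes)) norm <- norm[genes, , drop = FALSE]
  log2(norm[, tum, drop = FALSE] + 1)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config) {
  if (is.null(config$simulate)) {
    log_msg("INFO", "simulate: external input_dir supplied, nothing to do")
    return(invisible(NULL))
  }
  ds <- generate_dataset(do.call(synthetic_config, config$simulate))
  manifest <- write_fixture(ds, file.path(config$out_dir, "input"))
  log_msg("INFO", "simulate: wrote %d files to %s", nrow(manifest),
          file.path(config$out_dir, "input"))
  invisible(manifest)
}

#' @rdname run_pipeline
#' @export
stage_de <- function(config) {
  norm <- read_matrix_tsv(in_path(config, "expression_norm.tsv"))
  beta <- read_matrix_tsv(in_path(config, "methylation_beta.tsv"))
  conditions <- read_conditions(config)
  deg <- differential_expression(norm, conditions,
                                 min_median = config$min_median,
                                 lfc_cut = config$lfc_cut,
                                 fdr_cut = config$fdr_cut)
  dm <- differential_methylation(beta, conditions, q_cut = config$dm_q_cut,
                                 fdr_cut = config$dm_fdr_cut)
  write_tsv(deg, out_path(config, "deg.tsv"))
  write_tsv(dm, out_path(config, "dm.tsv"))
  log_msg("INFO", "de: %d DEGs (%d up, %d down), %d hyper / %d hypo promoters",
          sum(deg$status %in% c("up", "down")), sum(deg$status == "up"),
          sum(deg$status == "down"), sum(dm$direction == "hyper"),
          sum(dm$direction == "hypo"))
  invisible(list(deg = deg, dm = dm))
}

#' @rdname run_pipeline
#' @export
stage_modules <- function(config) {
  deg <- read_tsv_checked(out_path(config, "deg.tsv"),
                          c("gene_id", "status"))
  de_genes <- deg$gene_id[deg$status %in% c("up", "down")]
  if (length(de_genes) < 3)
    stop_input("fewer than 3 differentially expressed genes; no modules")
  expr <- tumor_log_expr(config, de_genes)
  sp <- pick_soft_power(expr, candidates = config$power_candidates,
                        r2_target = config$r2_target)
  power <- if (sp$warning) config$fallback_power else sp$power
  adj <- coexpression_adjacency(expr, power = power)
  tom <- tom_from_adjacency(adj, power = power)
  mods <- detect_modules(tom, min_size = config$min_module_size,
                         cut_height = config$cut_height)
  write_tsv(mods$assignments, out_path(config, "modules.tsv"))
  write_tsv(cbind(chosen = sp$fit$power == power, sp$fit),
            out_path(config, "soft_power.tsv"))
  summ <- data.frame(module_id = names(mods$modules),
                     n_genes = lengths(mods$modules),
                     mean_adjacency = unname(mods$mean_adjacency))
  write_tsv(summ, out_path(config, "module_summary.tsv"))
  log_msg("INFO", "modules: power %d (scale-free fit %.2f%s), %d modules",
          power, max(sp$fit$r_squared),
          if (sp$warning) ", below target; fallback power used" else "",
          length(mods$modules))
  invisible(mods)
}

read_modules_file <- function(config) {
  df <- read_tsv_checked(out_path(config, "modules.tsv"),
                         c("gene_id", "module_id"))
  ids <- setdiff(unique(df$module_id), "unassigned")
  ids <- ids[order(as.integer(sub("^M", "", ids)))]
  setNames(lapply(ids, function(i) df$gene_id[df$module_id == i]), ids)
}

#' @rdname run_pipeline
#' @export
stage_bn <- function(config) {
  modules <- read_modules_file(config)
  results <- list()
  for (i in seq_along(modules)) {
    id <- names(modules)[i]
    genes <- modules[[i]]
    if (length(genes) > config$max_bn_genes)
      stop_input(paste("module %s has %d genes, above max_bn_genes = %d;",
                       "raise max_bn_genes to proceed"),
                 id, length(genes), config$max_bn_genes)
    expr <- tumor_log_expr(config, genes)
    x <- t(expr)
    strengths <- bootstrap_edge_strength(
      x, R = config$bn_bootstrap, seed = config$seed + 1000 + i,
      restarts = config$bn_boot_restarts, max_parents = config$max_parents)
    cc <- cor(x)
    sel <- select_directed_edges(strengths, cc,
                                 strength_cut = config$strength_cut,
                                 cor_cut = config$cor_cut)
    dir.create(out_path(config, "networks", id), recursive = TRUE,
               showWarnings = FALSE)
    full <- strengths
    full$cor <- cc[cbind(full$from, full$to)]
    full$passed_strength <- full$strength >= config$strength_cut
    full$passed_coexpr <- abs(full$cor) >= config$cor_cut
    write_tsv(full, out_path(config, "networks", id, "bn_edges.tsv"))
    log_msg("INFO", "bn: %s, %d candidate pairs, %d retained directed edges",
            id, nrow(strengths), nrow(sel))
    results[[id]] <- sel
  }
  invisible(results)
}

#' @rdname run_pipeline
#' @export
stage_assemble <- function(config) {
  modules <- read_modules_file(config)
  annotation <- read_tsv_checked(in_path(config, "annotation.tsv"),
                                 c("gene_id", "biotype", "is_tf"))
  tft <- read_tf_targets(in_path(config, "tf_targets.tsv"))
  binding <- read_tsv_checked(in_path(config, "binding_scores.tsv"),
                              c("lncrna_gene_id", "protein_gene_id", "score"))
  deg <- read_tsv_checked(out_path(config, "deg.tsv"),
                          c("gene_id", "status"))
  dm <- read_tsv_checked(out_path(config, "dm.tsv"),
                         c("gene_id", "direction"))
  expr <- beta <- NULL
  if (config$prune_mode == "correlation") {
    conditions <- read_conditions(config)
    tum <- names(conditions)[conditions == "tumor"]
    expr <- read_matrix_tsv(in_path(config, "expression_norm.tsv"))[, tum]
    beta <- read_matrix_tsv(in_path(config, "methylation_beta.tsv"))[, tum]
  }
  networks <- list()
  summary_rows <- list()
  for (id in names(modules)) {
    genes <- modules[[id]]
    bn <- read_tsv_checked(out_path(config, "networks", id, "bn_edges.tsv"),
                           c("from", "to", "strength", "passed_strength",
                             "passed_coexpr"))
    bn <- bn[bn$passed_strength & bn$passed_coexpr, , drop = FALSE]
    net <- assemble_network(id, genes, bn, tf_target_edges(genes, tft),
                            binding, annotation, deg, dm,
                            min_score = config$min_binding,
                            prune_mode = config$prune_mode,
                            expr = expr, beta = beta)
    write_network(net, out_path(config, "networks", id))
    networks[[id]] <- net
    summary_rows[[id]] <- data.frame(
      module_id = id, n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
      pct_genes_retained = 100 * nrow(net$nodes) / length(genes),
      pct_lncrna = if (nrow(net$nodes))
        100 * mean(net$nodes$biotype == "lncRNA") else 0,
      n_edges_pruned = nrow(net$removed_edges), stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, summary_rows)
  write_tsv(summ, out_path(config, "networks_summary.tsv"))
  log_msg("INFO", "assemble: %d networks, %d total edges",
          length(networks), sum(summ$n_edges))
  invisible(networks)
}

## rebuild the assembled networks from their on-disk stage outputs
read_networks <- function(config) {
  modules <- read_modules_file(config)
  annotation <- read_tsv_checked(in_path(config, "annotation.tsv"),
                                 c("gene_id", "biotype", "is_tf"))
  networks <- list()
  for (id in names(modules)) {
    path <- out_path(config, "networks", id, "edges.tsv")
    edges <- read_tsv_checked(path, c("from", "to", "provenance", "strength"))
    in_net <- sort(unique(c(edges$from, edges$to)))
    ann <- annotation[match(in_net, annotation$gene_id), , drop = FALSE]
    networks[[id]] <- structure(
      list(module_id = id,
           nodes = data.frame(gene_id = in_net, biotype = ann$biotype,
                              is_tf = as.integer(ann$is_tf),
                              stringsAsFactors = FALSE),
           edges = edges, module_genes = modules[[id]],
           n_module_genes = length(modules[[id]])),
      class = "regulatory_network")
  }
  networks
}

#' @rdname run_pipeline
#' @export
stage_robustness <- function(config) {
  networks <- read_networks(config)
  networks <- Filter(function(n) nrow(n$nodes) > 0, networks)
  if (length(networks) == 0) stop_input("no non-empty networks to assess")
  reports <- list()
  rows <- list()
  for (i in seq_along(networks)) {
    id <- names(networks)[i]
    rep_i <- node_deletion_bootstrap(networks[[i]],
                                     fraction = config$deletion_fraction,
                                     iterations = config$robustness_iterations,
                                     seed = config$seed + 2000 + i)
    reports[[id]] <- rep_i
    if (nrow(rep_i$edges))
      rows[[id]] <- cbind(module_id = id, rep_i$edges)
  }
  summ <- preservation_summary(reports, k_list = c(70, 80))
  write_tsv(do.call(rbind, rows), out_path(config, "robustness.tsv"))
  write_tsv(summ$per_network, out_path(config, "robustness_summary.tsv"))
  write_tsv(summ$pooled, out_path(config, "robustness_pooled.tsv"))
  log_msg("INFO", "robustness: pooled median preserved fraction %.3f at k=80",
          summ$pooled$median_fraction[summ$pooled$k == 80])
  invisible(list(reports = reports, summary = summ))
}

#' @rdname run_pipeline
#' @export
stage_regulators <- function(config) {
  networks <- read_networks(config)
  tft <- read_tf_targets(in_path(config, "tf_targets.tsv"))
  annotation <- read_tsv_checked(in_path(config, "annotation.tsv"),
                                 c("gene_id", "biotype", "is_tf"))
  binding <- read_tsv_checked(in_path(config, "binding_scores.tsv"),
                              c("lncrna_gene_id", "protein_gene_id", "score"))
  deg <- read_tsv_checked(out_path(config, "deg.tsv"),
                          c("gene_id", "status"))
  mutations <- read_tsv_checked(in_path(config, "mutations.tsv"),
                                c("gene_id", "qvalue"))
  tf_report <- identify_key_tfs(networks, tft, deg, mutations,
                                alpha = config$alpha, mut_q = config$mut_q)
  lnc_report <- identify_key_lncrnas(networks, binding, annotation,
                                     min_score = config$min_binding)
  ## expression correlation of each key lncRNA with its retained targets,
  ## over tumor samples
  norm <- read_matrix_tsv(in_path(config, "expression_norm.tsv"))
  conditions <- read_conditions(config)
  tum <- names(conditions)[conditions == "tumor"]
  tg <- lnc_report$targets
  if (nrow(tg)) {
    pc <- pair_correlation(log2(norm + 1), tg[, c("lncrna", "target")], tum)
    tg$cor_tumor <- pc$pairs$cor
    median_cor <- pc$median_cor
  } else {
    tg$cor_tumor <- numeric(0)
    median_cor <- NA_real_
  }
  write_tsv(tf_report$enrichment, out_path(config, "enrichment.tsv"))
  write_tsv(tg, out_path(config, "key_lncrnas.tsv"))
  report <- list(key_tfs_in_network = tf_report$key_tfs_in_network,
                 enriched_only_tfs = tf_report$enriched_only_tfs,
                 key_tfs_outside = tf_report$key_tfs_outside,
                 key_lncrnas = unique(lnc_report$key_lncrnas$lncrna),
                 median_lncrna_target_cor = median_cor)
  jsonlite::write_json(report, out_path(config, "key_regulators.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("INFO", "regulators: %d key TFs in-network, %d key lncRNAs",
          length(report$key_tfs_in_network), length(report$key_lncrnas))
  invisible(c(tf_report, list(key_lncrnas = lnc_report$key_lncrnas,
                              lncrna_targets = tg,
                              median_lncrna_target_cor = median_cor)))
}

#' Run the full regulatory-network inference pipeline
#'
#' Executes, in order: simulate (optional), differential
#' expression/methylation, co-expression modules, Bayesian edge
#' learning, network assembly, robustness, and key-regulator
#' identification. Every stage writes its outputs under
#' `config$out_dir`, and each `stage_*` function can be re-run
#' separately on those files, reproducing the all-in-one results.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run summary (also written to
#'   `run_summary.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "de", "modules", "bn", "assemble", "robustness",
              "regulators")
  elapsed <- setNames(numeric(length(stages)), stages)
  results <- list()
  for (s in stages) {
    t0 <- proc.time()[["elapsed"]]
    results[[s]] <- tryCatch(
      switch(s,
             simulate = stage_simulate(config),
             de = stage_de(config),
             modules = stage_modules(config),
             bn = stage_bn(config),
             assemble = stage_assemble(config),
             robustness = stage_robustness(config),
             regulators = stage_regulators(config)),
      error = function(e) {
        summary <- list(failed_stage = s, error = conditionMessage(e),
                        config = unclass(config))
        jsonlite::write_json(summary,
                             out_path(config, "run_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
        stop(sprintf("stage '%s' failed: %s", s, conditionMessage(e)),
             call. = FALSE)
      })
    elapsed[s] <- proc.time()[["elapsed"]] - t0
  }
  deg <- results$de$deg
  nets <- results$assemble
  n_edges <- vapply(nets, function(n) nrow(n$edges), numeric(1))
  edge_prov <- unlist(lapply(nets, function(n) n$edges$provenance))
  summary <- list(
    genes_tested = sum(deg$status != "filtered_low_expression"),
    degs = sum(deg$status %in% c("up", "down")),
    modules = length(results$modules$modules),
    networks = length(nets),
    edges_total = sum(n_edges),
    edges_bayes = sum(grepl("bayes", edge_prov)),
    edges_tf_db = sum(grepl("tf_db", edge_prov)),
    edges_pruned = sum(vapply(nets, function(n) nrow(n$removed_edges),
                              numeric(1))),
    key_tfs_in_network = length(results$regulators$key_tfs_in_network),
    key_tfs_outside = length(results$regulators$key_tfs_outside),
    key_lncrnas = nrow(unique(results$regulators$key_lncrnas["lncrna"])),
    median_preserved_rate = as.list(stats::setNames(
      results$robustness$summary$pooled$median_fraction,
      paste0("k", results$robustness$summary$pooled$k))),
    elapsed_sec = as.list(round(elapsed, 2)),
    version = as.character(utils::packageVersion("lungregnet")),
    config = unclass(config))
  jsonlite::write_json(summary, out_path(config, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
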