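#' Configuration for the synthetic multi-omic generator
#'
#' Builds and validates the parameter set for [generate_dataset()]. The
#' defaults describe a desk-scale tumor/normal cohort: five co-expression
#' modules of 40 genes planted in the tumor samples, a directed regulatory
#' structure inside each module (a mutated hub TF, a second non-mutated TF
#' and an lncRNA regulator, each with dedicated targets), a set of genes
#' silenced in tumor with coincident promoter hypermethylation, and a
#' binding-score table in which true lncRNA-protein pairs score high.
#'
#' @param n_genes total number of genes.
#' @param n_tf number of transcription factors (protein-coding).
#' @param n_lncrna number of lncRNA genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per module; `n_modules * module_size <= n_genes`.
#' @param n_normal,n_tumor sample counts per condition.
#' @param edge_effect linear coefficient of a regulator on its target's
#'   latent (log-scale) tumor expression.
#' @param noise_sd standard deviation of the latent log-scale noise.
#' @param n_silenced genes under-expressed in tumor with promoter
#'   hypermethylation.
#' @param delta_beta minimum average promoter beta gain of silenced genes.
#' @param n_driver_tf TFs carrying a significant somatic mutation
#'   (q < 0.05).
#' @param binding_score_true_mean,binding_score_null_mean means of the
#'   binding-score distributions (0-100 scale) for true and null
#'   lncRNA-protein pairs.
#' @param module_loading loading of each module gene on its latent module
#'   factor (tumor samples only).
#' @param de_lfc planted log2 fold change (tumor vs normal) of module genes.
#' @param silenced_lfc planted log2 fold change of silenced genes
#'   (must be <= -1 so tumor mean expression is at most half of normal).
#' @param binding_score_sd standard deviation of binding scores.
#' @param seed integer seed; the generator is a pure function of the
#'   config including this seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 240, n_tf = 15, n_lncrna = 10,
                             n_modules = 5, module_size = 40,
                             n_normal = 30, n_tumor = 30,
                             edge_effect = 0.8, noise_sd = 0.5,
                             n_silenced = 10, delta_beta = 0.3,
                             n_driver_tf = 5,
                             binding_score_true_mean = 60,
                             binding_score_null_mean = 10,
                             module_loading = 0.8, de_lfc = 1.5,
                             silenced_lfc = -2.5, binding_score_sd = 8,
                             seed = 7) {
  cfg <- as.list(environment())
  chk <- function(ok, msg) if (!ok) stop_input("invalid config: %s", msg)
  chk(n_genes >= 1, "n_genes must be a positive integer")
  chk(n_modules >= 1, "n_modules must be a positive integer")
  chk(module_size >= 1, "module_size must be a positive integer")
  chk(n_modules * module_size <= n_genes,
      "n_modules * module_size must not exceed n_genes")
  chk(n_tf >= 0 && n_tf <= n_genes, "n_tf must be between 0 and n_genes")
  chk(n_lncrna >= 0 && n_lncrna <= n_genes - n_tf,
      "n_lncrna must leave room for the TFs within n_genes")
  chk(n_silenced >= 0 && n_silenced <= n_genes,
      "n_silenced must be between 0 and n_genes")
  chk(n_driver_tf >= 0 && n_driver_tf <= n_tf,
      "n_driver_tf must not exceed n_tf")
  chk(n_normal >= 2 && n_tumor >= 2, "need at least 2 samples per condition")
  chk(edge_effect > 0, "edge_effect must be strictly positive")
  chk(noise_sd > 0, "noise_sd must be strictly positive")
  chk(module_loading > 0, "module_loading must be strictly positive")
  chk(binding_score_sd > 0, "binding_score_sd must be strictly positive")
  chk(delta_beta > 0 && delta_beta < 1, "delta_beta must be in (0, 1)")
  chk(silenced_lfc <= -1,
      "silenced_lfc must be <= -1 (tumor mean at most half of normal)")
  chk(is.numeric(seed) && length(seed) == 1, "seed must be a single integer")
  structure(cfg, class = "synthetic_config")
}

## Deterministic role layout. Local positions inside each module:
##   1            hub TF (driver while supply lasts)
##   2..15        hub targets (ends of the list silenced first)
##   16           lncRNA regulator, 17..19 its protein-coding targets
##   20           second (non-driver) TF, 21..26 its targets
##   27           extra lncRNA without out-edges
## Leftover TFs/lncRNAs go to the unassigned pool; silenced genes overflow
## into plain module genes (highest free local positions), then the pool.
plan_layout <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_mod_genes <- cfg$n_modules * cfg$module_size
  module_of <- setNames(rep("unassigned", cfg$n_genes), genes)
  module_of[seq_len(n_mod_genes)] <-
    sprintf("P%d", rep(seq_len(cfg$n_modules), each = cfg$module_size))
  gid <- function(m, local) genes[(m - 1) * cfg$module_size + local]
  ms <- cfg$module_size
  ht <- min(14, ms - 1)

  tfs <- character(0); lncs <- character(0)
  edges_from <- character(0); edges_to <- character(0)
  add_edges <- function(from, to) {
    edges_from <<- c(edges_from, rep(from, length(to)))
    edges_to <<- c(edges_to, to)
  }
  taken <- setNames(rep(FALSE, cfg$n_genes), genes)

  hub_targets <- vector("list", cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    if (length(tfs) < cfg$n_tf && ms >= 2) {
      hub <- gid(m, 1); tfs <- c(tfs, hub); taken[hub] <- TRUE
      tg <- gid(m, seq(2, 1 + ht)); taken[tg] <- TRUE
      hub_targets[[m]] <- tg
      add_edges(hub, tg)
    }
  }
  for (m in seq_len(cfg$n_modules)) {
    if (length(lncs) < cfg$n_lncrna && ms >= 19) {
      ln <- gid(m, 16); lncs <- c(lncs, ln); taken[ln] <- TRUE
      tg <- gid(m, 17:19); taken[tg] <- TRUE
      add_edges(ln, tg)
    }
  }
  for (m in seq_len(cfg$n_modules)) {
    if (length(tfs) < cfg$n_tf && ms >= 26) {
      tf2 <- gid(m, 20); tfs <- c(tfs, tf2); taken[tf2] <- TRUE
      tg <- gid(m, 21:26); taken[tg] <- TRUE
      add_edges(tf2, tg)
    }
  }
  for (m in seq_len(cfg$n_modules)) {
    if (length(lncs) < cfg$n_lncrna && ms >= 27) {
      ln <- gid(m, 27); lncs <- c(lncs, ln); taken[ln] <- TRUE
    }
  }
  pool <- genes[module_of == "unassigned"]
  pool_free <- pool[!taken[pool]]
  need_tf <- cfg$n_tf - length(tfs)
  if (need_tf > 0) {
    if (need_tf > length(pool_free))
      stop_input("invalid config: not enough unassigned genes for %d extra TFs",
                 need_tf)
    extra <- pool_free[seq_len(need_tf)]
    tfs <- c(tfs, extra); taken[extra] <- TRUE
    pool_free <- setdiff(pool_free, extra)
  }
  need_lnc <- cfg$n_lncrna - length(lncs)
  if (need_lnc > 0) {
    if (need_lnc > length(pool_free))
      stop_input("invalid config: not enough unassigned genes for %d extra lncRNAs",
                 need_lnc)
    extra <- pool_free[seq_len(need_lnc)]
    lncs <- c(lncs, extra); taken[extra] <- TRUE
    pool_free <- setdiff(pool_free, extra)
  }

  ## silenced: ends of hub-target lists first (round-robin over modules),
  ## then plain module genes, then the pool
  silenced <- character(0)
  if (cfg$n_silenced > 0) {
    per_mod <- lapply(hub_targets, rev)
    k <- 1
    while (length(silenced) < cfg$n_silenced && any(lengths(per_mod) > 0)) {
      m <- ((k - 1) %% cfg$n_modules) + 1
      if (length(per_mod[[m]]) > 0) {
        silenced <- c(silenced, per_mod[[m]][1])
        per_mod[[m]] <- per_mod[[m]][-1]
      }
      k <- k + 1
    }
    if (length(silenced) < cfg$n_silenced) {
      plain <- rev(genes[module_of != "unassigned"])
      plain <- plain[!taken[plain] & !(plain %in% silenced)]
      extra <- utils::head(plain, cfg$n_silenced - length(silenced))
      silenced <- c(silenced, extra)
    }
    if (length(silenced) < cfg$n_silenced) {
      extra <- utils::head(pool_free, cfg$n_silenced - length(silenced))
      silenced <- c(silenced, extra)
    }
  }
  drivers <- utils::head(tfs, cfg$n_driver_tf)

  list(genes = genes, module_of = module_of, tfs = tfs, lncrnas = lncs,
       silenced = silenced, drivers = drivers,
       planted_edges = data.frame(from = edges_from, to = edges_to,
                                  stringsAsFactors = FALSE))
}

#' Generate a synthetic multi-omic dataset with planted ground truth
#'
#' Simulates matched tumor/normal expression counts (log-normal latent
#' model, Poisson sampling), gene-level promoter methylation betas, a
#' per-gene somatic-mutation significance table, a TF-to-target map, an
#' lncRNA-protein binding-score table and a gene annotation table. Tumor
#' samples carry a latent factor per module (block correlation), planted
#' directed regulator-target effects, silenced genes with promoter
#' hypermethylation, and driver TFs with significant mutations. The
#' result is a pure function of the config, including its seed.
#'
#' Latent model, per tumor sample: module genes without a planted
#' regulator have log-expression `loading * factor + noise`; a planted
#' target instead inherits `edge_effect * regulator + noise`. Normal
#' samples are pure noise. Log-normal means are corrected by half the
#' latent variance so that planted fold changes hold on the count scale.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_dataset`: list with elements
#'   `expression_counts`, `expression_norm` (counts-per-million),
#'   `methylation_beta`, `conditions`, `mutation_table`, `tf_targets`,
#'   `binding_scores`, `annotation` and `truth`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    lay <- plan_layout(cfg)
    genes <- lay$genes
    n_genes <- cfg$n_genes
    samples <- c(sprintf("N%03d", seq_len(cfg$n_normal)),
                 sprintf("T%03d", seq_len(cfg$n_tumor)))
    conditions <- setNames(rep(c("normal", "tumor"),
                               c(cfg$n_normal, cfg$n_tumor)), samples)

    ## planted per-gene log2 fold change: module genes alternate up/down
    ## (real modules mix over- and under-expressed genes, and a balanced
    ## design keeps sequencing-depth normalisation identifiable)
    lfc <- setNames(rep(0, n_genes), genes)
    in_mod <- lay$module_of != "unassigned"
    local_idx <- ((seq_len(n_genes) - 1) %% cfg$module_size) + 1
    lfc[in_mod] <- ifelse(local_idx[in_mod] %% 2 == 1, cfg$de_lfc,
                          -cfg$de_lfc)
    lfc[lay$silenced] <- cfg$silenced_lfc

    ## topological order over planted edges (depth checked, not assumed)
    pe <- lay$planted_edges
    indeg <- setNames(rep(0L, n_genes), genes)
    if (nrow(pe)) {
      tab <- table(pe$to)
      indeg[names(tab)] <- as.integer(tab)
    }
    topo <- character(0)
    frontier <- genes[indeg == 0]
    indeg_w <- indeg
    while (length(frontier)) {
      topo <- c(topo, frontier)
      if (nrow(pe)) {
        out <- pe[pe$from %in% frontier, , drop = FALSE]
        indeg_w[out$to] <- indeg_w[out$to] - 1L
        frontier <- unique(out$to[indeg_w[out$to] == 0])
      } else frontier <- character(0)
    }
    stopifnot(length(topo) == n_genes)  # planted edges form a DAG

    mu <- setNames(rnorm(n_genes, log(150), 0.5), genes)
    has_reg <- setNames(rep(FALSE, n_genes), genes)
    if (nrow(pe)) has_reg[unique(pe$to)] <- TRUE

    ## tumor latent values u: module factor for free module genes,
    ## regulator inheritance for planted targets, noise for everyone;
    ## planted fold changes act on the log (median) scale
    u <- matrix(0, n_genes, cfg$n_tumor, dimnames = list(genes, NULL))
    fac <- matrix(rnorm(cfg$n_modules * cfg$n_tumor), cfg$n_modules)
    eps_t <- matrix(rnorm(n_genes * cfg$n_tumor, 0, cfg$noise_sd), n_genes,
                    dimnames = list(genes, NULL))
    mod_idx <- match(lay$module_of, sprintf("P%d", seq_len(cfg$n_modules)))
    names(mod_idx) <- genes
    for (g in topo) {
      u[g, ] <- eps_t[g, ]
      if (has_reg[g]) {
        regs <- pe$from[pe$to == g]
        for (r in regs)
          u[g, ] <- u[g, ] + cfg$edge_effect * u[r, ]
      } else if (!is.na(mod_idx[g])) {
        u[g, ] <- u[g, ] + cfg$module_loading * fac[mod_idx[g], ]
      }
    }

    z_norm <- mu +
      matrix(rnorm(n_genes * cfg$n_normal, 0, cfg$noise_sd), n_genes)
    z_tum <- mu + lfc * log(2) + u
    lambda <- cbind(exp(z_norm), exp(z_tum))
    counts <- matrix(rpois(length(lambda), lambda), n_genes,
                     dimnames = list(genes, samples))
    norm <- normalize_counts(counts)

    ## promoter methylation betas
    base_beta <- pmin(pmax(rnorm(n_genes, 0.25, 0.05), 0.05), 0.6)
    beta <- matrix(rnorm(n_genes * length(samples), 0, 0.03), n_genes,
                   dimnames = list(genes, samples)) + base_beta
    tum_cols <- conditions == "tumor"
    beta[lay$silenced, tum_cols] <- beta[lay$silenced, tum_cols] +
      cfg$delta_beta + 0.05
    beta <- pmin(pmax(beta, 0.001), 0.999)

    ## mutation significance (driver prediction consumed as an input)
    is_driver <- genes %in% lay$drivers
    qv <- ifelse(is_driver, runif(n_genes, 0, 0.0499),
                 runif(n_genes, 0.05, 1))
    nmut <- ifelse(is_driver, 1L + rpois(n_genes, 2), rpois(n_genes, 0.6))
    mutation_table <- data.frame(gene_id = genes, n_mutations = nmut,
                                 qvalue = qv, stringsAsFactors = FALSE)

    ## TF-target map: planted TF edges + decoy targets in other modules
    tf_edge <- pe[pe$from %in% lay$tfs, , drop = FALSE]
    decoys <- list()
    mod_genes_all <- genes[lay$module_of != "unassigned"]
    for (tf in lay$tfs) {
      own <- if (!is.na(mod_idx[tf]))
        genes[!is.na(mod_idx) & mod_idx == mod_idx[tf]] else character(0)
      cand <- setdiff(mod_genes_all, c(own, tf))
      k <- if (tf %in% tf_edge$from) 3 else min(8, length(cand))
      if (k > 0 && length(cand) > 0)
        decoys[[tf]] <- data.frame(from = tf,
                                   to = sample(cand, min(k, length(cand))),
                                   stringsAsFactors = FALSE)
    }
    tf_targets <- unique(rbind(tf_edge, do.call(rbind, decoys)))
    tf_targets <- tf_targets[order(tf_targets$from, tf_targets$to), ,
                             drop = FALSE]
    names(tf_targets) <- c("tf_gene_id", "target_gene_id")
    rownames(tf_targets) <- NULL

    ## binding scores: true lncRNA->protein pairs high, null pairs low
    lnc_edge <- pe[pe$from %in% lay$lncrnas, , drop = FALSE]
    true_pairs <- lnc_edge
    rows <- list()
    if (nrow(true_pairs))
      rows[["true"]] <- data.frame(
        lncrna_gene_id = true_pairs$from, protein_gene_id = true_pairs$to,
        score = rnorm(nrow(true_pairs), cfg$binding_score_true_mean,
                      cfg$binding_score_sd),
        stringsAsFactors = FALSE)
    protein_genes <- setdiff(genes, lay$lncrnas)
    for (ln in lay$lncrnas) {
      cand <- setdiff(protein_genes, true_pairs$to[true_pairs$from == ln])
      k <- min(3, length(cand))
      if (k > 0)
        rows[[ln]] <- data.frame(
          lncrna_gene_id = ln, protein_gene_id = sample(cand, k),
          score = rnorm(k, cfg$binding_score_null_mean, cfg$binding_score_sd),
          stringsAsFactors = FALSE)
    }
    binding <- if (length(rows)) do.call(rbind, rows) else
      data.frame(lncrna_gene_id = character(0),
                 protein_gene_id = character(0), score = numeric(0))
    binding$score <- pmin(pmax(binding$score, 0), 100)
    binding <- binding[order(binding$lncrna_gene_id, binding$protein_gene_id), ,
                       drop = FALSE]
    rownames(binding) <- NULL

    annotation <- data.frame(
      gene_id = genes, symbol = genes,
      biotype = ifelse(genes %in% lay$lncrnas, "lncRNA", "protein_coding"),
      is_tf = as.integer(genes %in% lay$tfs),
      chrom = paste0("chr", (seq_len(n_genes) - 1) %% 22 + 1),
      tss = 100000L + 5000L * seq_len(n_genes),
      strand = rep(c("+", "-"), length.out = n_genes),
      stringsAsFactors = FALSE)

    truth <- list(module_of = lay$module_of,
                  planted_edges = pe,
                  silenced_genes = lay$silenced,
                  driver_tfs = lay$drivers,
                  true_binding_pairs = setNames(lnc_edge,
                                                c("lncrna_gene_id",
                                                  "protein_gene_id")))
    structure(list(config = cfg,
                   expression_counts = counts,
                   expression_norm = norm,
                   methylation_beta = beta,
                   conditions = conditions,
                   mutation_table = mutation_table,
                   tf_targets = tf_targets,
                   binding_scores = binding,
                   annotation = annotation,
                   truth = truth),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic multi-omic dataset: %d genes x %d samples (%d normal, %d tumor)\n",
    nrow(x$expression_counts), ncol(x$expression_counts),
    sum(x$conditions == "normal"), sum(x$conditions == "tumor")))
  cat(sprintf("  modules: %d planted | TFs: %d | lncRNAs: %d | silenced: %d\n",
              x$config$n_modules, x$config$n_tf, x$config$n_lncrna,
              length(x$truth$silenced_genes)))
  cat(sprintf("  planted directed edges: %d | binding pairs: %d\n",
              nrow(x$truth$planted_edges), nrow(x$truth$true_binding_pairs)))
  invisible(x)
}

#' Write a synthetic dataset as the pipeline's TSV inputs
#'
#' Serialises every input table in the schema the pipeline reads
#' (`expression_counts.tsv`, `expression_norm.tsv`, `methylation_beta.tsv`,
#' `samples.tsv`, `annotation.tsv`, `mutations.tsv`, `tf_targets.tsv`,
#' `binding_scores.tsv`) plus the ground truth under `truth/`, which no
#' downstream stage reads.
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if absent).
#' @return invisibly, a manifest data frame (file, n_rows, md5).
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop_input("cannot create directory %s", directory)
  dir.create(file.path(directory, "truth"), showWarnings = FALSE)
  d <- dataset
  files <- list(
    "expression_counts.tsv" = function(p) write_matrix_tsv(d$expression_counts, p),
    "expression_norm.tsv"   = function(p) write_matrix_tsv(d$expression_norm, p),
    "methylation_beta.tsv"  = function(p) write_matrix_tsv(d$methylation_beta, p),
    "samples.tsv" = function(p) write_tsv(
      data.frame(sample_id = names(d$conditions), condition = d$conditions,
                 stringsAsFactors = FALSE), p),
    "annotation.tsv" = function(p) write_tsv(d$annotation, p),
    "mutations.tsv" = function(p) write_tsv(d$mutation_table, p),
    "tf_targets.tsv" = function(p) write_tsv(d$tf_targets, p),
    "binding_scores.tsv" = function(p) write_tsv(d$binding_scores, p),
    "truth/module_of.tsv" = function(p) write_tsv(
      data.frame(gene_id = names(d$truth$module_of),
                 module_id = d$truth$module_of, stringsAsFactors = FALSE), p),
    "truth/planted_edges.tsv" = function(p) write_tsv(d$truth$planted_edges, p),
    "truth/silenced_genes.tsv" = function(p) write_tsv(
      data.frame(gene_id = d$truth$silenced_genes, stringsAsFactors = FALSE), p),
    "truth/driver_tfs.tsv" = function(p) write_tsv(
      data.frame(gene_id = d$truth$driver_tfs, stringsAsFactors = FALSE), p),
    "truth/true_binding_pairs.tsv" = function(p) write_tsv(
      d$truth$true_binding_pairs, p))
  n_rows <- integer(0); md5 <- character(0)
  for (f in names(files)) {
    p <- file.path(directory, f)
    files[[f]](p)
    n_rows <- c(n_rows, length(readLines(p)) - 1L)
    md5 <- c(md5, unname(tools::md5sum(p)))
  }
  manifest <- data.frame(file = names(files), n_rows = n_rows, md5 = md5,
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(directory, "manifest.tsv"))
  invisible(manifest)
}

#' Read a dataset written by [write_fixture()]
#'
#' Validates each file's schema (a missing required column is an error
#' naming the column) and reassembles a `synthetic_dataset`-shaped list.
#' Ground-truth files are read only if present.
#'
#' @param directory directory written by [write_fixture()].
#' @return list with the same data fields as [generate_dataset()] output.
#' @export
read_dataset <- function(directory) {
  counts <- read_matrix_tsv(file.path(directory, "expression_counts.tsv"))
  norm <- read_matrix_tsv(file.path(directory, "expression_norm.tsv"))
  beta <- read_matrix_tsv(file.path(directory, "methylation_beta.tsv"))
  smp <- read_tsv_checked(file.path(directory, "samples.tsv"),
                          c("sample_id", "condition"))
  conditions <- setNames(smp$condition, smp$sample_id)
  ann <- read_tsv_checked(file.path(directory, "annotation.tsv"),
                          c("gene_id", "symbol", "biotype", "is_tf",
                            "chrom", "tss", "strand"))
  mut <- read_tsv_checked(file.path(directory, "mutations.tsv"),
                          c("gene_id", "n_mutations", "qvalue"))
  tft <- read_tf_targets(file.path(directory, "tf_targets.tsv"))
  bnd <- read_tsv_checked(file.path(directory, "binding_scores.tsv"),
                          c("lncrna_gene_id", "protein_gene_id", "score"))
  out <- list(expression_counts = counts, expression_norm = norm,
              methylation_beta = beta, conditions = conditions,
              mutation_table = mut, tf_targets = tft, binding_scores = bnd,
              annotation = ann)
  tdir <- file.path(directory, "truth")
  if (dir.exists(tdir)) {
    mo <- read_tsv_checked(file.path(tdir, "module_of.tsv"),
                           c("gene_id", "module_id"))
    out$truth <- list(
      module_of = setNames(mo$module_id, mo$gene_id),
      planted_edges = read_tsv_checked(file.path(tdir, "planted_edges.tsv"),
                                       c("from", "to")),
      silenced_genes = read_tsv_checked(file.path(tdir, "silenced_genes.tsv"),
                                        "gene_id")$gene_id,
      driver_tfs = read_tsv_checked(file.path(tdir, "driver_tfs.tsv"),
                                    "gene_id")$gene_id,
      true_binding_pairs = read_tsv_checked(
        file.path(tdir, "true_binding_pairs.tsv"),
        c("lncrna_gene_id", "protein_gene_id")))
  }
  out
}

#' Read and validate a TF-target interaction map
#'
#' Two-column TSV (`tf_gene_id`, `target_gene_id`); self-targeting rows
#' are rejected at load time.
#'
#' @param path TSV path.
#' @return data frame with columns `tf_gene_id`, `target_gene_id`.
#' @export
read_tf_targets <- function(path) {
  df <- read_tsv_checked(path, c("tf_gene_id", "target_gene_id"))
  bad <- df$tf_gene_id == df$target_gene_id
  if (any(bad))
    stop_input("tf_targets: TF %s maps to itself (self-target not allowed)",
               df$tf_gene_id[which(bad)[1]])
  df
}
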