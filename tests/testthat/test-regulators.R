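test_that("fisher enrichment reproduces worked 2x2 tables", {
  ## balanced table: no association
  u <- sprintf("u%02d", 1:20)
  er <- fisher_enrichment("tf", network_genes = u[1:10],
                          targets = u[c(1:5, 11:15)], universe = u)
  expect_equal(c(er$a, er$b, er$c, er$d), c(5, 5, 5, 5))
  expect_equal(er$odds_ratio, 1)
  expect_equal(er$pvalue, 1)

  ## a=3,b=0,c=0,d=3: two-sided p by the point-probability rule = 0.1
  v <- sprintf("v%d", 1:6)
  er2 <- fisher_enrichment("tf", network_genes = v[1:3], targets = v[1:3],
                           universe = v)
  expect_equal(er2$pvalue, 0.1, tolerance = 1e-12)

  ## odds ratio arithmetic without zero cells
  w <- sprintf("w%03d", 1:100)
  er3 <- fisher_enrichment("tf", network_genes = w[1:20],
                           targets = w[c(1:10, 21:30)], universe = w)
  expect_equal(c(er3$a, er3$b, er3$c, er3$d), c(10, 10, 10, 70))
  expect_equal(er3$odds_ratio, 7)
  expect_error(fisher_enrichment("tf", w[1:3], w[1:2], character(0)),
               "universe")
})

test_that("fisher p matches enumeration and fisher.test on random tables", {
  withr::local_seed(6)
  for (i in 1:200) {
    tab <- as.integer(sample(0:12, 4, replace = TRUE))
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if (a + b + c + d == 0) next
    p_pkg <- lungregnet:::fisher_two_sided(a, b, c, d)
    expect_equal(p_pkg, fisher_enum(a, b, c, d), tolerance = 1e-12)
    p_ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-8)
  }
})

test_that("the odds ratio is invariant under simultaneous transposition", {
  withr::local_seed(9)
  for (i in 1:50) {
    t4 <- sample(0:9, 4, replace = TRUE)
    or1 <- lungregnet:::odds_ratio_2x2(t4[1], t4[2], t4[3], t4[4])
    or2 <- lungregnet:::odds_ratio_2x2(t4[1], t4[3], t4[2], t4[4])
    expect_equal(or1, or2, tolerance = 1e-12)
  }
})

fixture_networks <- function(ds) {
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  mod <- ds$truth$module_of
  nets <- list()
  for (m in sort(unique(mod[mod != "unassigned"]))) {
    genes <- names(mod)[mod == m]
    nets[[m]] <- assemble_network(m, genes, NULL,
                                  tf_target_edges(genes, ds$tf_targets),
                                  ds$binding_scores, ds$annotation, deg, dm)
  }
  list(nets = nets, deg = deg, dm = dm)
}

test_that("planted driver TFs are identified as in-network key TFs", {
  ds <- default_dataset()
  fx <- fixture_networks(ds)
  rep <- identify_key_tfs(fx$nets, ds$tf_targets, fx$deg, ds$mutation_table)
  expect_true(all(ds$truth$driver_tfs %in% rep$key_tfs_in_network))
  ## non-driver in-module TFs are enriched but not mutated
  tf2 <- setdiff(ds$annotation$gene_id[ds$annotation$is_tf == 1 &
                                         ds$truth$module_of != "unassigned"],
                 ds$truth$driver_tfs)
  expect_true(all(tf2 %in% rep$enriched_only_tfs))
  ## report is consistent with its defining predicates
  mut_sig <- ds$mutation_table$gene_id[ds$mutation_table$qvalue < 0.05]
  for (tf in rep$key_tfs_in_network) {
    rows <- rep$enrichment[rep$enrichment$tf == tf, ]
    expect_true(any(rows$pvalue < 0.05))
    expect_true(any(rows$in_network))
    expect_true(tf %in% mut_sig)
  }
})

test_that("removing the mutation moves a driver to the enriched-only list", {
  ds <- default_dataset()
  fx <- fixture_networks(ds)
  mut <- ds$mutation_table
  drv <- ds$truth$driver_tfs[1]
  mut$qvalue[mut$gene_id == drv] <- 0.5
  rep <- identify_key_tfs(fx$nets, ds$tf_targets, fx$deg, mut)
  expect_false(drv %in% rep$key_tfs_in_network)
  expect_true(drv %in% rep$enriched_only_tfs)
})

test_that("a TF with no targets in the universe is skipped with a warning", {
  ds <- default_dataset()
  fx <- fixture_networks(ds)
  map <- rbind(ds$tf_targets,
               data.frame(tf_gene_id = "G0240", target_gene_id = "ZZZZ"))
  expect_warning(identify_key_tfs(fx$nets, map, fx$deg, ds$mutation_table),
                 "G0240")
})

test_that("an unchanged mutated TF regulating a network is flagged outside", {
  ## constructed case: TF "O" is ns in the DEG table, mutated, and all its
  ## targets sit inside the single network
  u <- sprintf("u%02d", 1:40)
  net <- structure(list(module_id = "M1",
                        nodes = data.frame(gene_id = u[1:10],
                                           biotype = "protein_coding",
                                           is_tf = 0L),
                        edges = data.frame(from = u[1], to = u[2:10],
                                           provenance = "tf_db",
                                           strength = NA_real_),
                        module_genes = u[1:20], n_module_genes = 20),
                   class = "regulatory_network")
  map <- data.frame(tf_gene_id = "O", target_gene_id = u[1:6])
  deg <- data.frame(gene_id = c(u, "O"), status = c(rep("up", 40), "ns"))
  mut <- data.frame(gene_id = c(u, "O"), qvalue = c(rep(1, 40), 0.01))
  rep <- identify_key_tfs(list(M1 = net), map, deg, mut,
                          universe = u[1:20])
  expect_true("O" %in% rep$key_tfs_outside)
  expect_false("O" %in% rep$key_tfs_in_network)
})

test_that("key lncRNAs need a retained, score-supported protein target", {
  ann <- data.frame(gene_id = c("L", "L2", "P", "Q"),
                    biotype = c("lncRNA", "lncRNA", "protein_coding",
                                "protein_coding"),
                    is_tf = 0L)
  mk_net <- function(edges) structure(
    list(module_id = "M1",
         nodes = data.frame(gene_id = unique(c(edges$from, edges$to)),
                            biotype = ann$biotype[match(
                              unique(c(edges$from, edges$to)), ann$gene_id)],
                            is_tf = 0L),
         edges = cbind(edges, provenance = "bayes", strength = 0.9),
         module_genes = ann$gene_id, n_module_genes = 4),
    class = "regulatory_network")
  binding <- data.frame(lncrna_gene_id = "L", protein_gene_id = "P",
                        score = 30)
  ## protein target with score 30 -> key
  r1 <- identify_key_lncrnas(list(M1 = mk_net(data.frame(from = "L", to = "P"))),
                             binding, ann)
  expect_equal(r1$key_lncrnas$lncrna, "L")
  ## only lncRNA targets -> no protein binding evidence -> not key
  r2 <- identify_key_lncrnas(list(M1 = mk_net(data.frame(from = "L", to = "L2"))),
                             binding, ann)
  expect_equal(nrow(r2$key_lncrnas), 0)
})

test_that("planted lncRNA regulators are recovered with high precision", {
  ds <- default_dataset()
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  mod <- ds$truth$module_of
  tum <- names(ds$conditions)[ds$conditions == "tumor"]
  nets <- list()
  for (i in seq_len(5)) {
    m <- paste0("P", i)
    genes <- names(mod)[mod == m]
    x <- t(log2(ds$expression_norm[genes, tum] + 1))
    bs <- bootstrap_edge_strength(x, R = 100, seed = 100 + i)
    sel <- select_directed_edges(bs, cor(x))
    nets[[m]] <- assemble_network(m, genes, sel,
                                  tf_target_edges(genes, ds$tf_targets),
                                  ds$binding_scores, ds$annotation, deg, dm)
  }
  rep <- identify_key_lncrnas(nets, ds$binding_scores, ds$annotation)
  found <- unique(rep$key_lncrnas$lncrna)
  true_reg <- unique(ds$truth$true_binding_pairs$lncrna_gene_id)
  expect_gt(length(found), 0)
  precision <- mean(found %in% true_reg)
  expect_gte(precision, 0.8)
})

test_that("pair correlations handle exact and degenerate cases", {
  expr <- rbind(a = 1:10, b = 2 * (1:10), c = 10:1, d = rep(5, 10))
  colnames(expr) <- paste0("s", 1:10)
  pc <- pair_correlation(expr, data.frame(g1 = c("a", "a", "a"),
                                          g2 = c("b", "c", "d")))
  expect_equal(pc$pairs$cor[1], 1)
  expect_equal(pc$pairs$cor[2], -1)
  expect_true(is.na(pc$pairs$cor[3]))
  expect_equal(pc$median_cor, 0)  # median of {1, -1}, NA excluded
  expect_error(pair_correlation(expr, data.frame(g1 = "a", g2 = "zz")),
               "absent")
  expect_error(pair_correlation(expr, data.frame(g1 = "a", g2 = "b"),
                                samples = c("s1", "s2")), "3 samples")
})
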