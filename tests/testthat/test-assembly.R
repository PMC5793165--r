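make_annotation <- function(genes, lnc = character(0), tfs = character(0)) {
  data.frame(gene_id = genes, symbol = genes,
             biotype = ifelse(genes %in% lnc, "lncRNA", "protein_coding"),
             is_tf = as.integer(genes %in% tfs), stringsAsFactors = FALSE)
}

test_that("TF-target edges require both endpoints in the module", {
  map <- data.frame(tf_gene_id = c("A", "A", "B"),
                    target_gene_id = c("B", "X", "C"))
  ed <- tf_target_edges(c("A", "B", "C"), map)
  expect_setequal(paste(ed$from, ed$to), c("A B", "B C"))
  expect_true(all(ed$provenance == "tf_db"))
  expect_equal(nrow(tf_target_edges(c("Y", "Z"), map)), 0)
})

test_that("self-targeting interaction maps are rejected at load time", {
  dir <- withr::local_tempdir()
  write.table(data.frame(tf_gene_id = c("A", "B"),
                         target_gene_id = c("B", "B")),
              file.path(dir, "tft.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_tf_targets(file.path(dir, "tft.tsv")), "self-target")
})

test_that("binding filter keeps score >= 25 and drops the rest", {
  ann <- make_annotation(c("L1", "L2", "P1", "P2"), lnc = c("L1", "L2"))
  binding <- data.frame(lncrna_gene_id = c("L1", "L1"),
                        protein_gene_id = c("P1", "P2"),
                        score = c(25.0, 24.9))
  edges <- data.frame(from = c("L1", "L1", "L1", "P1"),
                      to = c("P1", "P2", "L2", "P2"))
  out <- lncrna_binding_filter(edges, binding, ann)
  keys <- paste(out$from, out$to)
  expect_true("L1 P1" %in% keys)     # exactly 25: real binding
  expect_false("L1 P2" %in% keys)    # 24.9: below threshold
  expect_true("L1 L2" %in% keys)     # lncRNA target: filter out of scope
  expect_true("P1 P2" %in% keys)     # protein source: untouched
  ## a missing score counts as below threshold
  edges2 <- data.frame(from = "L2", to = "P1")
  expect_equal(nrow(lncrna_binding_filter(edges2, binding, ann)), 0)
})

test_that("methylation pruning removes edges into silenced targets only", {
  deg <- data.frame(gene_id = c("A", "B", "C", "D"),
                    status = c("up", "down", "down", "up"))
  dm <- data.frame(gene_id = c("A", "B", "C", "D"),
                   direction = c("hyper", "hyper", "ns", "ns"))
  edges <- data.frame(from = c("A", "A", "A", "B"),
                      to = c("B", "C", "D", "A"))
  pr <- methylation_prune(edges, deg, dm)
  expect_equal(paste(pr$removed$from, pr$removed$to), "A B")  # down & hyper
  expect_setequal(paste(pr$edges$from, pr$edges$to),
                  c("A C", "A D", "B A"))  # down-only, up-hyper, up kept
  expect_match(pr$removed$reason, "hypermethylation")
  expect_error(methylation_prune(edges, deg, dm, mode = "nonsense"),
               "mode")
})

test_that("correlation-mode pruning needs matrices and uses the threshold", {
  deg <- data.frame(gene_id = c("A", "B"), status = c("up", "down"))
  dm <- data.frame(gene_id = c("A", "B"), direction = c("ns", "ns"))
  edges <- data.frame(from = "A", to = "B")
  expect_error(methylation_prune(edges, deg, dm, mode = "correlation"),
               "requires")
  expr <- rbind(A = 1:10, B = 10:1)
  beta <- rbind(A = seq(0.1, 0.2, length.out = 10), B = seq(0.1, 1, length.out = 10))
  pr <- methylation_prune(edges, deg, dm, mode = "correlation",
                          expr = expr, beta = beta)
  expect_equal(nrow(pr$removed), 1)  # B expression anti-correlated with beta
})

test_that("assembly merges provenance, filters, and drops isolated genes", {
  genes <- c("T", "X", "Y", "Z")
  ann <- make_annotation(genes, tfs = "T")
  deg <- data.frame(gene_id = genes, status = c("up", "up", "down", "up"))
  dm <- data.frame(gene_id = genes, direction = c("ns", "ns", "hyper", "ns"))
  bn <- data.frame(from = c("T", "X"), to = c("X", "Y"),
                   strength = c(0.9, 0.8))
  tf <- data.frame(from = "T", to = "X")
  net <- assemble_network("M1", genes, bn, tf,
                          binding = data.frame(lncrna_gene_id = character(0),
                                               protein_gene_id = character(0),
                                               score = numeric(0)),
                          annotation = ann, deg = deg, dm = dm)
  ## T->X from both sources: one edge, provenance union, strength kept
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$provenance, "bayes,tf_db")
  expect_equal(net$edges$strength, 0.9)
  ## X->Y pruned (Y down+hyper); Y and Z isolated and dropped
  expect_setequal(net$nodes$gene_id, c("T", "X"))
  expect_equal(paste(net$removed_edges$from, net$removed_edges$to), "X Y")
})

test_that("an edge endpoint outside the module is an input error", {
  ann <- make_annotation(c("A", "B"))
  deg <- data.frame(gene_id = c("A", "B"), status = c("up", "up"))
  dm <- data.frame(gene_id = c("A", "B"), direction = c("ns", "ns"))
  bn <- data.frame(from = "A", to = "Q", strength = 0.9)
  expect_error(assemble_network("M1", c("A", "B"), bn, bn[0, ],
                                binding = data.frame(lncrna_gene_id = character(0),
                                                     protein_gene_id = character(0),
                                                     score = numeric(0)),
                                annotation = ann, deg = deg, dm = dm),
               "outside the module")
})

test_that("a module with no surviving edges gives an empty network", {
  ann <- make_annotation(c("A", "B"))
  deg <- data.frame(gene_id = c("A", "B"), status = c("up", "down"))
  dm <- data.frame(gene_id = c("A", "B"), direction = c("ns", "hyper"))
  bn <- data.frame(from = "A", to = "B", strength = 0.8)
  net <- assemble_network("M1", c("A", "B"), bn, bn[0, ],
                          binding = data.frame(lncrna_gene_id = character(0),
                                               protein_gene_id = character(0),
                                               score = numeric(0)),
                          annotation = ann, deg = deg, dm = dm)
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("binding filter and methylation prune commute", {
  ds <- default_dataset()
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  mod <- ds$truth$module_of
  genes <- names(mod)[mod == "P1"]
  edges <- tf_target_edges(genes, ds$tf_targets)
  ## add lncRNA out-edges so both filters have work to do
  lnc <- ds$annotation$gene_id[ds$annotation$biotype == "lncRNA" &
                                 ds$annotation$gene_id %in% genes]
  extra <- data.frame(from = lnc[1], to = genes[2:6], provenance = "bayes")
  all_e <- rbind(edges, extra)
  f1 <- methylation_prune(lncrna_binding_filter(all_e, ds$binding_scores,
                                                ds$annotation),
                          deg, dm)$edges
  f2 <- lncrna_binding_filter(methylation_prune(all_e, deg, dm)$edges,
                              ds$binding_scores, ds$annotation)
  expect_equal(f1[order(f1$from, f1$to), c("from", "to")],
               f2[order(f2$from, f2$to), c("from", "to")],
               ignore_attr = TRUE)
})

test_that("planted TF edges into silenced genes are excluded on the fixture", {
  ds <- default_dataset()
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  mod <- ds$truth$module_of
  genes <- names(mod)[mod == "P1"]
  hub <- genes[1]
  tf_e <- tf_target_edges(genes, ds$tf_targets)
  hub_edges <- tf_e[tf_e$from == hub, ]
  sil_in_module <- intersect(ds$truth$silenced_genes, hub_edges$to)
  expect_length(sil_in_module, 2)
  net <- assemble_network("P1", genes, NULL, tf_e, ds$binding_scores,
                          ds$annotation, deg, dm)
  expect_equal(sum(net$edges$from == hub),
               sum(hub_edges$from == hub) - length(sil_in_module))
  expect_false(any(net$edges$to %in% ds$truth$silenced_genes))
})

test_that("every retained node has degree >= 1 and dropped nodes had zero", {
  ds <- default_dataset()
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  mod <- ds$truth$module_of
  for (m in c("P1", "P3")) {
    genes <- names(mod)[mod == m]
    net <- assemble_network(m, genes, NULL, tf_target_edges(genes, ds$tf_targets),
                            ds$binding_scores, ds$annotation, deg, dm)
    degs <- table(factor(c(net$edges$from, net$edges$to),
                         levels = net$nodes$gene_id))
    expect_true(all(degs >= 1))
    dropped <- setdiff(genes, net$nodes$gene_id)
    expect_false(any(dropped %in% c(net$edges$from, net$edges$to)))
  }
})

test_that("network export writes edges, SIF and GraphML", {
  dir <- withr::local_tempdir()
  ds <- default_dataset()
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  mod <- ds$truth$module_of
  genes <- names(mod)[mod == "P1"]
  net <- assemble_network("P1", genes, NULL, tf_target_edges(genes, ds$tf_targets),
                          ds$binding_scores, ds$annotation, deg, dm)
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  sif <- readLines(file.path(dir, "network.sif"))
  expect_length(sif, nrow(net$edges))
  expect_match(sif[1], "\tregulates\t")
  g <- igraph::read_graph(file.path(dir, "network.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
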