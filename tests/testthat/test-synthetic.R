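test_that("generation is a pure function of the config", {
  cfg <- synthetic_config(n_genes = 60, n_modules = 2, module_size = 20,
                          n_tf = 4, n_lncrna = 2, n_silenced = 4,
                          n_driver_tf = 2, n_normal = 6, n_tumor = 6,
                          seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expression_counts, d2$expression_counts)
  expect_identical(d1$methylation_beta, d2$methylation_beta)
  expect_identical(d1$binding_scores, d2$binding_scores)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(synthetic_config(n_genes = 60, n_modules = 2,
                                          module_size = 20, n_tf = 4,
                                          n_lncrna = 2, n_silenced = 4,
                                          n_driver_tf = 2, n_normal = 6,
                                          n_tumor = 6, seed = 12))
  expect_false(identical(d1$expression_counts, d3$expression_counts))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_dataset(synthetic_config(n_genes = 30, n_modules = 1,
                                              module_size = 10, n_tf = 1,
                                              n_lncrna = 0, n_silenced = 0,
                                              n_driver_tf = 1, n_normal = 4,
                                              n_tumor = 4)))
  expect_identical(.Random.seed, before)
})

test_that("a config without lncRNAs yields no binding rows or lncRNA annotation", {
  ds <- generate_dataset(synthetic_config(n_genes = 60, n_modules = 2,
                                          module_size = 20, n_tf = 4,
                                          n_lncrna = 0, n_silenced = 2,
                                          n_driver_tf = 2, n_normal = 5,
                                          n_tumor = 5))
  expect_equal(nrow(ds$binding_scores), 0)
  expect_false(any(ds$annotation$biotype == "lncRNA"))
})

test_that("invalid configs fail naming the violated invariant", {
  expect_error(synthetic_config(n_modules = 10, module_size = 40,
                                n_genes = 100),
               "n_modules \\* module_size")
  expect_error(synthetic_config(n_driver_tf = 20, n_tf = 5), "n_driver_tf")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(delta_beta = 1.2), "delta_beta")
  expect_error(synthetic_config(edge_effect = -1), "edge_effect")
})

test_that("tumor samples show block correlation by planted module", {
  ds <- default_dataset()
  tum <- names(ds$conditions)[ds$conditions == "tumor"]
  mod <- ds$truth$module_of
  mg <- names(mod)[mod != "unassigned"]
  cc <- cor(t(log2(ds$expression_norm[mg, tum] + 1)))
  same <- outer(mod[mg], mod[mg], "==")
  ut <- upper.tri(cc)
  gap <- mean(abs(cc[same & ut])) - mean(abs(cc[!same & ut]))
  expect_gte(gap, 0.3)
})

test_that("planted edges point within modules and correlate positively in tumor", {
  ds <- generate_dataset(synthetic_config(n_tumor = 200))
  pe <- ds$truth$planted_edges
  mod <- ds$truth$module_of
  expect_true(all(pe$from != pe$to))
  expect_true(all(mod[pe$from] == mod[pe$to]))
  tum <- names(ds$conditions)[ds$conditions == "tumor"]
  le <- log2(ds$expression_norm[, tum] + 1)
  r <- vapply(seq_len(nrow(pe)),
              function(i) cor(le[pe$from[i], ], le[pe$to[i], ]), numeric(1))
  expect_true(all(r > 0))
})

test_that("silenced genes are halved in tumor with a promoter beta gain", {
  ds <- default_dataset()
  sg <- ds$truth$silenced_genes
  expect_length(sg, 10)
  nrm <- ds$conditions == "normal"
  tum <- ds$conditions == "tumor"
  ratio <- rowMeans(ds$expression_counts[sg, tum]) /
    rowMeans(ds$expression_counts[sg, nrm])
  expect_true(all(ratio <= 0.5))
  gain <- rowMeans(ds$methylation_beta[sg, tum]) -
    rowMeans(ds$methylation_beta[sg, nrm])
  expect_true(all(gain >= 0.3))
})

test_that("silencing predicate separates silenced from unperturbed genes", {
  ds <- default_dataset()
  deg <- differential_expression(ds$expression_norm, ds$conditions)
  dm <- differential_methylation(ds$methylation_beta, ds$conditions)
  flagged <- intersect(deg$gene_id[deg$status == "down"],
                       dm$gene_id[dm$direction == "hyper"])
  expect_setequal(flagged, ds$truth$silenced_genes)
})

test_that("mutation q-values split drivers from the rest at 0.05", {
  ds <- default_dataset()
  mt <- ds$mutation_table
  drv <- mt$gene_id %in% ds$truth$driver_tfs
  expect_true(all(mt$qvalue[drv] < 0.05))
  expect_true(all(mt$qvalue[!drv] >= 0.05))
})

test_that("binding scores separate true from null pairs", {
  ds <- default_dataset()
  bs <- ds$binding_scores
  truth_key <- paste(ds$truth$true_binding_pairs$lncrna_gene_id,
                     ds$truth$true_binding_pairs$protein_gene_id)
  is_true <- paste(bs$lncrna_gene_id, bs$protein_gene_id) %in% truth_key
  expect_true(all(bs$score >= 0 & bs$score <= 100))
  expect_gt(min(bs$score[is_true]), max(0, mean(bs$score[!is_true])))
  expect_true(all(bs$score[is_true] >= 25))
})

test_that("fixtures round-trip through disk with schema validation", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_config(n_genes = 60, n_modules = 2,
                                          module_size = 20, n_tf = 4,
                                          n_lncrna = 2, n_silenced = 2,
                                          n_driver_tf = 2, n_normal = 5,
                                          n_tumor = 5))
  manifest <- write_fixture(ds, dir)
  expect_equal(manifest$n_rows[manifest$file == "expression_counts.tsv"], 60)
  expect_equal(manifest$n_rows[manifest$file == "samples.tsv"], 10)
  expect_equal(manifest$n_rows[manifest$file == "mutations.tsv"], 60)
  expect_true(all(nchar(manifest$md5) == 32))

  back <- read_dataset(dir)
  expect_equal(back$expression_counts, ds$expression_counts)
  expect_equal(back$expression_norm, ds$expression_norm, tolerance = 1e-8)
  expect_equal(back$methylation_beta, ds$methylation_beta, tolerance = 1e-8)
  expect_identical(back$conditions, ds$conditions)
  expect_equal(back$tf_targets, ds$tf_targets)
  expect_equal(back$truth$silenced_genes, ds$truth$silenced_genes)

  ## dropping a required column must fail naming it
  ann <- read.delim(file.path(dir, "annotation.tsv"))
  ann$biotype <- NULL
  write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(dir), "biotype")
})

test_that("identical configs serialize byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 40, n_modules = 1, module_size = 30,
                          n_tf = 2, n_lncrna = 1, n_silenced = 2,
                          n_driver_tf = 1, n_normal = 5, n_tumor = 5)
  m1 <- write_fixture(generate_dataset(cfg), d1)
  m2 <- write_fixture(generate_dataset(cfg), d2)
  expect_identical(m1$md5, m2$md5)
})
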