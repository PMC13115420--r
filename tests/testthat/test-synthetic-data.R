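test_that("generators are byte-deterministic under a fixed config and seed", {
  cfg <- small_sim_config(seed = 11)
  a1 <- generate_disease_associations(cfg)
  a2 <- generate_disease_associations(cfg)
  expect_identical(a1, a2)

  sets <- list(shared = attr(a1, "shared"), A = attr(a1, "A_only"),
               B = attr(a1, "B_only"))
  p1 <- generate_target_predictions(cfg, sets$shared, sets$A, sets$B)
  p2 <- generate_target_predictions(cfg, sets$shared, sets$A, sets$B)
  expect_identical(p1, p2)

  lib1 <- generate_gmt_library(cfg, sets$shared)
  lib2 <- generate_gmt_library(cfg, sets$shared)
  expect_identical(lib1, lib2)
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(lib1, f1); write_gmt(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))

  q1 <- generate_qpcr_dataset(cfg)
  expect_identical(q1, generate_qpcr_dataset(cfg))

  nodes <- make_gene_ids(50)
  e1 <- generate_interactome(cfg, nodes)
  expect_identical(e1, generate_interactome(cfg, nodes))
})

test_that("generator streams are independent: one generator does not perturb another", {
  cfg <- small_sim_config(seed = 3)
  q_alone <- generate_qpcr_dataset(cfg)
  a <- generate_disease_associations(cfg)
  q_after <- generate_qpcr_dataset(cfg)
  expect_identical(q_alone, q_after)
})

test_that("association table realizes configured set sizes exactly, recounted from rows", {
  cfg <- small_sim_config(seed = 7, n_genes_universe = 100,
                          disease_A_size = 10, disease_B_size = 12,
                          overlap_size = 4, n_terms_A = 3, n_terms_B = 2)
  tab <- generate_disease_associations(cfg)
  # brute-force set arithmetic on the emitted rows only
  a_genes <- unique(tab$gene_id[tab$disease_label == cfg$disease_A_label])
  b_genes <- unique(tab$gene_id[tab$disease_label == cfg$disease_B_label])
  expect_length(a_genes, 10)
  expect_length(b_genes, 12)
  expect_length(intersect(a_genes, b_genes), 4)
  # every term non-empty, scores and source classes well-formed
  expect_setequal(unique(tab$term_id[tab$disease_label == cfg$disease_A_label]),
                  sprintf("A_TERM_%02d", 1:3))
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  expect_true(all(tab$source_class %in% c("curated", "literature")))
})

test_that("zero overlap gives disjoint unions and oversized overlap errors", {
  cfg0 <- small_sim_config(overlap_size = 0L)
  tab <- generate_disease_associations(cfg0)
  a_genes <- unique(tab$gene_id[tab$disease_label == cfg0$disease_A_label])
  b_genes <- unique(tab$gene_id[tab$disease_label == cfg0$disease_B_label])
  expect_length(intersect(a_genes, b_genes), 0)
  expect_error(small_sim_config(overlap_size = 35L), "overlap_size")
})

test_that("planted miRNAs hit shared genes at the planted binomial rate", {
  counts <- unlist(lapply(1:8, function(s) {
    cfg <- small_sim_config(seed = s, n_genes_universe = 400,
                            disease_A_size = 150, disease_B_size = 150,
                            overlap_size = 100,
                            planted_shared_target_prob = 0.5,
                            background_target_prob = 0.05)
    tab <- generate_disease_associations(cfg)
    preds <- generate_target_predictions(cfg, attr(tab, "shared"),
                                         attr(tab, "A_only"),
                                         attr(tab, "B_only"))
    planted <- attr(preds, "planted_mirnas")
    vapply(planted, function(m) {
      length(intersect(unique(preds$gene_id[preds$mirna_id == m]),
                       attr(tab, "shared")))
    }, 1L)
  }))
  # mean of Binomial(100, 0.5) draws; 24 draws => SE ~ 1
  expect_gt(mean(counts), 45)
  expect_lt(mean(counts), 55)
})

test_that("source attribution: no dropout lists every pair in all sources; pairs always keep one source", {
  cfg <- small_sim_config(source_dropout = 0)
  tab <- generate_disease_associations(cfg)
  preds <- generate_target_predictions(cfg, attr(tab, "shared"),
                                       attr(tab, "A_only"),
                                       attr(tab, "B_only"))
  per_pair <- table(paste(preds$mirna_id, preds$gene_id))
  expect_true(all(per_pair == cfg$n_sources))

  cfg_hi <- small_sim_config(source_dropout = 0.95)
  preds_hi <- generate_target_predictions(cfg_hi, attr(tab, "shared"),
                                          attr(tab, "A_only"),
                                          attr(tab, "B_only"))
  expect_true(all(table(paste(preds_hi$mirna_id, preds_hi$gene_id)) >= 1))
  expect_error(generate_target_predictions(cfg, character(), "g1", "g2"),
               "empty gene set")
})

test_that("without planted miRNAs no shared count exceeds the null binomial bound", {
  exceed <- 0L
  for (s in 1:20) {
    cfg <- small_sim_config(seed = s, n_planted_top = 0L,
                            background_target_prob = 0.08)
    tab <- generate_disease_associations(cfg)
    shared <- attr(tab, "shared")
    preds <- generate_target_predictions(cfg, shared, attr(tab, "A_only"),
                                         attr(tab, "B_only"))
    counts <- vapply(split(preds$gene_id, preds$mirna_id), function(g) {
      length(intersect(unique(g), shared))
    }, 1L)
    bound <- qbinom(1 - 1e-6, length(shared), cfg$background_target_prob)
    exceed <- exceed + sum(counts > bound)
  }
  expect_identical(exceed, 0L)
})

test_that("GMT generator plants the most-enriched term and validates sizes", {
  cfg <- small_sim_config(seed = 5)
  pool <- make_gene_ids(cfg$n_genes_universe)[1:25]
  lib <- generate_gmt_library(cfg, pool)
  expect_length(lib, cfg$n_library_terms)
  expect_true(all(lengths(lib) >= 10 & lengths(lib) <= 20))
  # enrichment oracle: the planted term must attain the smallest
  # hypergeometric p against a query equal to the pool
  p <- vapply(lib, function(genes) {
    hyper_upper_oracle(length(intersect(pool, genes)), length(genes),
                       length(pool), cfg$n_genes_universe)
  }, 1)
  expect_identical(names(which.min(p)), attr(lib, "planted_terms")[1])
  expect_error(generate_gmt_library(cfg, character()), "non-empty")
  expect_error(
    generate_gmt_library(small_sim_config(library_term_size = c(10L, 300L)),
                         pool),
    "universe|size")
})

test_that("interactome generator: simple graph, confidences in range, planted hubs lead", {
  cfg <- small_sim_config()
  nodes <- make_gene_ids(120)
  edges <- generate_interactome(cfg, nodes)
  expect_true(all(edges$gene_a < edges$gene_b))
  expect_false(any(duplicated(edges[c("gene_a", "gene_b")])))
  expect_true(all(edges$confidence >= 0 & edges$confidence <= 1))
  deg <- degree_oracle(nodes, edges$gene_a, edges$gene_b)
  top3 <- names(sort(deg, decreasing = TRUE))[1:3]
  expect_setequal(top3, attr(edges, "planted_hubs"))
  expect_error(generate_interactome(cfg, nodes[1:2]), "planted hubs")
})

test_that("two-node preferential-attachment graph has the single possible edge", {
  cfg <- small_sim_config(n_planted_hubs = 2L)
  edges <- generate_interactome(cfg, c("GA", "GB"))
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$gene_a, "GA")
  expect_identical(edges$gene_b, "GB")
})

test_that("configuration model reproduces a prescribed degree sequence", {
  cfg <- small_sim_config(network_model = "configuration")
  nodes <- make_gene_ids(12)
  degs <- c(3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L)
  edges <- generate_interactome(cfg, nodes, degree_sequence = degs)
  recount <- degree_oracle(nodes, edges$gene_a, edges$gene_b)
  expect_identical(unname(recount), degs)
  expect_error(generate_interactome(cfg, nodes), "degree")
})

test_that("noise-free qPCR data returns the planted fold exactly", {
  q <- qpcr_config(
    plasma_log2_effects = list(
      "hsa-miR-16-5p" = c(control = 0, PD = 0, glioma = log2(3.24))),
    tissue_log2_effects = list(),
    sd_ct = 0, reference_sd = 0, spike_sd = 0, n_per_group = 4)
  cfg <- small_sim_config(qpcr = q)
  ct <- generate_qpcr_dataset(cfg)
  plasma <- ct[ct$compartment == "plasma", ]
  rel <- relative_expression_table(plasma, calibrator_group = "control")
  means <- tapply(rel$ratio[rel$analyte == "hsa-miR-16-5p"],
                  rel$group[rel$analyte == "hsa-miR-16-5p"], mean)
  # Ct values are emitted at instrument resolution (3 decimals), so the
  # noise-free recovery is exact to ~2^0.001
  expect_equal(unname(means[["glioma"]] / means[["control"]]), 3.24,
               tolerance = 1e-3)
  # all other analytes planted flat: every ratio is 1
  flat <- rel$ratio[rel$analyte != "hsa-miR-16-5p"]
  expect_equal(flat, rep(1, length(flat)), tolerance = 1e-3)
})

test_that("planted undetectable analytes exceed the Ct cutoff and drop to NA", {
  q <- qpcr_config(
    analytes_plasma = c("hsa-miR-16-5p", "hsa-miR-124-3p"),
    undetectable_plasma = "hsa-miR-124-3p",
    plasma_log2_effects = list(), tissue_log2_effects = list(),
    n_per_group = 3)
  cfg <- small_sim_config(qpcr = q)
  ct <- generate_qpcr_dataset(cfg)
  und <- ct[ct$analyte == "hsa-miR-124-3p" & ct$compartment == "plasma", ]
  expect_true(all(und$ct > 40))
  rel <- relative_expression_table(ct[ct$compartment == "plasma", ],
                                   calibrator_group = "control")
  expect_true(all(is.na(rel$ratio[rel$analyte == "hsa-miR-124-3p"])))
  expect_error(qpcr_config(efficiencies = 2.5), "efficienc")
})
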