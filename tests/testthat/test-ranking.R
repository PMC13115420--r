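test_that("aggregate_predictions keeps multi-source pairs with their source counts", {
  preds <- tibble::tibble(
    mirna_id = c("m1", "m1", "m1", "m1", "m2"),
    gene_id = c("g1", "g1", "g1", "g2", "g1"),
    source_db = c("s1", "s2", "s3", "s1", "s1"))
  out <- aggregate_predictions(preds, min_sources = 2)
  expect_identical(nrow(out), 1L)
  expect_identical(out$n_sources, 3L)

  all_pairs <- aggregate_predictions(preds, min_sources = 1)
  expect_identical(nrow(all_pairs), 3L)
  expect_error(aggregate_predictions(preds, min_sources = 0))
})

test_that("aggregation matches a brute-force group-and-count oracle", {
  set.seed(9)
  for (k in 1:3) {
    preds <- data.frame(
      mirna_id = sample(paste0("m", 1:6), 120, replace = TRUE),
      gene_id = sample(paste0("g", 1:10), 120, replace = TRUE),
      source_db = sample(paste0("s", 1:5), 120, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- as.data.frame(aggregate_predictions(preds, min_sources = k))
    want <- aggregate_oracle(preds, k)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("count_targets counts distinct targets inside the gene set", {
  pairs <- tibble::tibble(mirna_id = c("m1", "m1", "m1", "m2"),
                          gene_id = c("g1", "g2", "g9", "g7"))
  counts <- count_targets(pairs, c("g1", "g9", "g4"))
  expect_identical(counts, c(m1 = 2L, m2 = 0L))
})

test_that("ranking of the published count table puts miR-16-5p first with 483", {
  tab <- tibble::as_tibble(read.delim(table1_path()))
  ranked <- rank_mirnas(tab)
  expect_identical(ranked$mirna_id[1], "hsa-miR-16-5p")
  expect_identical(ranked$n_shared[1], 483L)
  expect_identical(ranked$rank, 1:14)
  # top decile of 14 records is ceil(1.4) = 2
  expect_identical(nrow(select_top_decile(ranked)), 2L)
})

test_that("rank ties fall back to n_B, n_A then lexicographic id", {
  recs <- tibble::tibble(
    mirna_id = c("m-c", "m-a", "m-b", "m-d"),
    n_shared = c(5L, 5L, 5L, 9L),
    n_B = c(2L, 2L, 3L, 0L),
    n_A = c(1L, 1L, 0L, 0L))
  ranked <- rank_mirnas(recs)
  expect_identical(ranked$mirna_id, c("m-d", "m-b", "m-a", "m-c"))

  flat <- tibble::tibble(mirna_id = c("m-c", "m-a", "m-b"),
                         n_shared = c(3L, 3L, 3L))
  expect_identical(rank_mirnas(flat)$mirna_id, c("m-a", "m-b", "m-c"))
})

test_that("ranking matches an order() oracle on random counts", {
  set.seed(17)
  for (i in 1:20) {
    recs <- tibble::tibble(
      mirna_id = paste0("m", sample(100:999, 25)),
      n_shared = sample(0:50, 25, replace = TRUE),
      n_B = sample(0:80, 25, replace = TRUE),
      n_A = sample(0:60, 25, replace = TRUE))
    got <- rank_mirnas(recs)$mirna_id
    want <- recs$mirna_id[order(-recs$n_shared, -recs$n_B, -recs$n_A,
                                recs$mirna_id)]
    expect_identical(got, want)
  }
})

test_that("top-decile selection matches a percentile oracle", {
  expect_identical(
    nrow(select_top_decile(rank_mirnas(
      tibble::tibble(mirna_id = paste0("m", 1:10),
                     n_shared = 10:1)))), 1L)
  set.seed(5)
  recs <- tibble::tibble(mirna_id = sprintf("m%03d", 1:200),
                         n_shared = sample(0:500, 200, replace = TRUE))
  ranked <- rank_mirnas(recs)
  top <- select_top_decile(ranked)
  expect_identical(nrow(top), 20L)
  expect_true(min(top$n_shared) >= max(ranked$n_shared[-(1:20)]))
})

test_that("pathway annotation reports sorted pipe-joined intersections", {
  pairs <- tibble::tibble(mirna_id = "miR-x",
                          gene_symbol = c("PTEN", "PINK1", "AKT1"))
  pw <- list("PTEN/PINK1-PARK6-parkin" = c("PINK1", "PTEN", "PRKN",
                                           "PARK7", "LRRK2"),
             unrelated = c("ZZZ3", "ZZZ4"))
  ann <- annotate_pathways(pairs, pw)
  hit <- ann[ann$pathway == "PTEN/PINK1-PARK6-parkin", ]
  expect_identical(hit$genes, "PINK1|PTEN")
  expect_identical(hit$n, 2L)
  miss <- ann[ann$pathway == "unrelated", ]
  expect_identical(miss$genes, "")
  expect_identical(miss$n, 0L)
  # random-input oracle
  set.seed(31)
  for (i in 1:20) {
    tg <- sample(LETTERS, 8)
    pwg <- sample(LETTERS, 10)
    got <- annotate_pathways(
      tibble::tibble(mirna_id = "m", gene_symbol = tg),
      list(p = pwg))
    expect_identical(got$genes, paste(sort(intersect(tg, pwg)),
                                      collapse = "|"))
  }
})

test_that("OneR-style binning orders four equal-frequency clusters with tied values together", {
  counts <- c(483L, 470L, 449L, 422L, 415L, 414L, 408L, 379L, 375L, 369L,
              365L, 358L, 353L, 338L)
  cl <- oner_cluster(counts)
  expect_identical(sort(unique(cl)), 1:4)
  expect_identical(cl[counts == 483L], 1L)
  expect_identical(cl[counts == 338L], 4L)
  # monotone: counts non-increasing across cluster boundaries
  ord <- order(-counts)
  expect_true(all(diff(cl[ord]) >= 0))

  expect_message(flat <- oner_cluster(rep(7L, 6)), "empty")
  expect_identical(flat, rep(1L, 6))
  expect_error(oner_cluster(c(1, 2, 3), n_clusters = 4), "at least")
})

test_that("OneR binning is monotone on random inputs", {
  set.seed(23)
  for (i in 1:50) {
    x <- sample(0:30, sample(4:40, 1), replace = TRUE)
    cl <- oner_cluster(x)
    ord <- order(-x)
    expect_true(all(diff(cl[ord]) >= 0))
    # tied values always share a cluster
    expect_true(all(tapply(cl, x, function(v) length(unique(v))) == 1L))
  }
})

test_that("ranking is invariant to duplicating a source database at min_sources 1", {
  cfg <- small_sim_config(seed = 19)
  tab <- generate_disease_associations(cfg)
  preds <- generate_target_predictions(cfg, attr(tab, "shared"),
                                       attr(tab, "A_only"),
                                       attr(tab, "B_only"))
  dup <- preds[preds$source_db == "srcdb_01", ]
  dup$source_db <- "srcdb_dup"
  both <- rbind(preds, dup)
  shared <- attr(tab, "shared")
  uA <- union(shared, attr(tab, "A_only"))
  uB <- union(shared, attr(tab, "B_only"))
  r1 <- rank_mirnas(mirna_rank_records(aggregate_predictions(preds),
                                       shared, uA, uB))
  r2 <- rank_mirnas(mirna_rank_records(aggregate_predictions(both),
                                       shared, uA, uB))
  expect_identical(r1$mirna_id, r2$mirna_id)
  expect_identical(r1$n_shared, r2$n_shared)
})

test_that("per-miRNA counts satisfy the recount identity over the set partition", {
  cfg <- small_sim_config(seed = 29)
  tab <- generate_disease_associations(cfg)
  shared <- attr(tab, "shared")
  a_only <- attr(tab, "A_only")
  b_only <- attr(tab, "B_only")
  preds <- generate_target_predictions(cfg, shared, a_only, b_only)
  pairs <- aggregate_predictions(preds)
  n_sh <- count_targets(pairs, shared)
  n_a <- count_targets(pairs, a_only)
  n_b <- count_targets(pairs, b_only)
  n_all <- count_targets(pairs, c(shared, a_only, b_only))
  expect_identical(n_sh + n_a + n_b, n_all)
})
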