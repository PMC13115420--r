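# small-scale simulation configs used across tests

small_sim_config <- function(seed = 7L, ...) {
  args <- list(
    seed = seed,
    n_genes_universe = 200L,
    disease_A_size = 30L, disease_B_size = 40L, overlap_size = 12L,
    n_terms_A = 4L, n_terms_B = 3L,
    n_mirnas = 20L, n_planted_top = 3L,
    planted_shared_target_prob = 0.6, background_target_prob = 0.08,
    n_sources = 5L, source_dropout = 0.3,
    n_library_terms = 8L, planted_enriched_terms = 1L,
    library_term_size = c(10L, 20L),
    qpcr = qpcr_config(n_per_group = 4L, n_tissue = 4L))
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

small_run_overrides <- function() {
  list(n_genes_universe = 500L,
       disease_A_size = 60L, disease_B_size = 80L, overlap_size = 25L,
       n_terms_A = 4L, n_terms_B = 3L,
       n_mirnas = 30L, n_planted_top = 3L,
       planted_shared_target_prob = 0.6, background_target_prob = 0.08,
       n_sources = 5L, library_term_size = c(10L, 20L))
}

# association tibble written to a temp TSV, returning the path
write_assoc_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

table1_path <- function() {
  system.file("extdata", "mirna_shared_target_counts.tsv",
              package = "sharedmiR")
}
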