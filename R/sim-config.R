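#' qPCR simulation settings
#'
#' Settings for the synthetic RT-qPCR Ct generator. Effects are planted on
#' the log2 expression scale relative to the calibrator group (plasma:
#' control/discopathy; tissue: peritumoral), and translated into Ct shifts of
#' \code{-effect / log2(E)} so that efficiency-adjusted relative
#' quantification recovers the planted fold change. The default planted
#' effects are the printed group-mean ratios of the study this pipeline
#' emulates: plasma miR-16-5p 1.76/2.0/5.7 and miR-32-5p 1.1/1.4/3.6
#' (control/PD/glioma), tissue miR-16-5p 1.6 vs 1.1 (tumor vs peritumoral).
#'
#' @param analytes_plasma mature miRNA ids measured in plasma.
#' @param analytes_tissue mature miRNA ids measured in tumor/peritumoral
#'   tissue.
#' @param plasma_log2_effects named list: analyte -> named numeric
#'   \code{c(control=, PD=, glioma=)} of log2 effects vs control.
#' @param tissue_log2_effects named list: analyte -> named numeric
#'   \code{c(peritumoral=, tumor=)} of log2 effects vs peritumoral.
#' @param undetectable_plasma analytes planted as undetectable (Ct > 40) in
#'   plasma.
#' @param sd_ct within-group biological + technical SD on the Ct scale
#'   (cycles).
#' @param reference_sd,spike_sd SD (cycles) of the endogenous reference (U6)
#'   and the exogenous spike-in (cel-miR-39-3p).
#' @param efficiencies named per-analyte amplification efficiencies in
#'   (1, 2.2]; unnamed scalar recycles to all analytes. Default 2 (perfect
#'   doubling).
#' @param reference_analyte,spike_analyte ids of the normalizer and spike-in.
#' @param baseline_ct named numeric \code{c(target=, reference=, spike=)}
#'   baseline cycle-threshold levels.
#' @param n_per_group plasma samples per group (control, PD, glioma).
#' @param n_tissue glioma patients with paired tumor/peritumoral samples.
#' @return a list of class \code{qpcr_config}.
#' @export
qpcr_config <- function(
    analytes_plasma = c("hsa-miR-16-5p", "hsa-miR-32-5p",
                        "hsa-miR-29a-3p", "hsa-miR-34a-5p"),
    analytes_tissue = c("hsa-miR-16-5p", "hsa-miR-32-5p", "hsa-miR-29a-3p",
                        "hsa-miR-34a-5p", "hsa-miR-124-3p",
                        "hsa-miR-548c-3p"),
    plasma_log2_effects = list(
      "hsa-miR-16-5p" = c(control = 0, PD = log2(2.0 / 1.76),
                          glioma = log2(5.7 / 1.76)),
      "hsa-miR-32-5p" = c(control = 0, PD = log2(1.4 / 1.1),
                          glioma = log2(3.6 / 1.1))),
    tissue_log2_effects = list(
      "hsa-miR-16-5p" = c(peritumoral = 0, tumor = log2(1.6 / 1.1))),
    undetectable_plasma = character(),
    sd_ct = 0.3,
    reference_sd = 0.15,
    spike_sd = 0.15,
    efficiencies = 2.0,
    reference_analyte = "U6",
    spike_analyte = "cel-miR-39-3p",
    baseline_ct = c(target = 28, reference = 20, spike = 22),
    n_per_group = 10,
    n_tissue = 10) {
  cfg <- list(
    analytes_plasma = analytes_plasma,
    analytes_tissue = analytes_tissue,
    plasma_log2_effects = plasma_log2_effects,
    tissue_log2_effects = tissue_log2_effects,
    undetectable_plasma = undetectable_plasma,
    sd_ct = sd_ct, reference_sd = reference_sd, spike_sd = spike_sd,
    efficiencies = efficiencies,
    reference_analyte = reference_analyte, spike_analyte = spike_analyte,
    baseline_ct = baseline_ct,
    n_per_group = n_per_group, n_tissue = n_tissue)
  class(cfg) <- "qpcr_config"
  validate_qpcr_config(cfg)
  cfg
}

validate_qpcr_config <- function(cfg) {
  eff <- cfg$efficiencies
  if (any(eff <= 1 | eff > 2.2)) {
    stop("amplification efficiencies must lie in (1, 2.2]", call. = FALSE)
  }
  stopifnot(cfg$sd_ct >= 0, cfg$reference_sd >= 0, cfg$spike_sd >= 0,
            cfg$n_per_group >= 1, cfg$n_tissue >= 1)
  invisible(cfg)
}

# per-analyte efficiency lookup, default 2.0 when the config omits one
analyte_efficiency <- function(cfg, analyte) {
  eff <- cfg$efficiencies
  if (is.null(names(eff))) return(rep_len(eff, length(analyte)))
  out <- unname(eff[analyte])
  out[is.na(out)] <- 2.0
  out
}

#' Simulation configuration with planted ground truth
#'
#' Central configuration for all synthetic-data generators. Defaults encode
#' the study scale this pipeline emulates: two diseases whose term-wise gene
#' unions have 2177 (disease A, 28 terms) and 3377 (disease B, 14 terms)
#' genes with an exactly planted intersection of 953; miRNA-target
#' predictions attributed across 14 source databases; a GMT library with
#' planted enriched terms; an interactome with planted hubs; and three-group
#' qPCR Ct data with planted log2 effects.
#'
#' @param seed integer master seed. Each generator derives its own RNG
#'   stream from \code{seed} plus a stable per-generator offset, so adding a
#'   generator never perturbs another's output.
#' @param n_genes_universe size of the gene universe (background for
#'   enrichment).
#' @param disease_A_size,disease_B_size,overlap_size gene-set sizes; the
#'   overlap is planted exactly, not sampled.
#' @param n_terms_A,n_terms_B disease terms per disease (every term
#'   non-empty).
#' @param n_mirnas,n_planted_top total miRNAs and how many are planted as
#'   high-shared-target miRNAs.
#' @param planted_shared_target_prob,background_target_prob per-gene
#'   targeting probabilities in (0,1): planted miRNAs sample shared genes
#'   with the former, everything else uses the latter.
#' @param n_sources,source_dropout number of prediction source databases and
#'   the per-source dropout probability; every emitted pair keeps at least
#'   one source.
#' @param n_library_terms,planted_enriched_terms,library_term_size GMT
#'   library shape: total terms, planted terms, and the inclusive size range
#'   terms are drawn from.
#' @param planted_member_frac minimum fraction of a planted term's members
#'   drawn from the planted gene pool.
#' @param network_model \code{"preferential_attachment"} or
#'   \code{"configuration"}.
#' @param n_planted_hubs hubs seeded as the initial core of the
#'   preferential-attachment graph.
#' @param pa_edges_per_node preferential-attachment edges per incoming node.
#' @param hub_attach_prob extra probability that each incoming node links to
#'   each planted hub, making the planted hubs the unambiguous top-degree
#'   ground truth.
#' @param qpcr a \code{\link{qpcr_config}}.
#' @param disease_A_label,disease_B_label labels used in emitted tables.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(
    seed = 1L,
    n_genes_universe = 20000L,
    disease_A_size = 2177L,
    disease_B_size = 3377L,
    overlap_size = 953L,
    n_terms_A = 28L,
    n_terms_B = 14L,
    n_mirnas = 140L,
    n_planted_top = 14L,
    planted_shared_target_prob = 0.5,
    background_target_prob = 0.05,
    n_sources = 14L,
    source_dropout = 0.3,
    n_library_terms = 20L,
    planted_enriched_terms = 2L,
    library_term_size = c(50L, 150L),
    planted_member_frac = 0.6,
    network_model = c("preferential_attachment", "configuration"),
    n_planted_hubs = 3L,
    pa_edges_per_node = 3L,
    hub_attach_prob = 0.25,
    qpcr = qpcr_config(),
    disease_A_label = "Parkinson disease",
    disease_B_label = "glioblastoma") {
  cfg <- list(
    seed = as.integer(seed),
    n_genes_universe = as.integer(n_genes_universe),
    disease_A_size = as.integer(disease_A_size),
    disease_B_size = as.integer(disease_B_size),
    overlap_size = as.integer(overlap_size),
    n_terms_A = as.integer(n_terms_A),
    n_terms_B = as.integer(n_terms_B),
    n_mirnas = as.integer(n_mirnas),
    n_planted_top = as.integer(n_planted_top),
    planted_shared_target_prob = planted_shared_target_prob,
    background_target_prob = background_target_prob,
    n_sources = as.integer(n_sources),
    source_dropout = source_dropout,
    n_library_terms = as.integer(n_library_terms),
    planted_enriched_terms = as.integer(planted_enriched_terms),
    library_term_size = as.integer(library_term_size),
    planted_member_frac = planted_member_frac,
    network_model = match.arg(network_model),
    n_planted_hubs = as.integer(n_planted_hubs),
    pa_edges_per_node = as.integer(pa_edges_per_node),
    hub_attach_prob = hub_attach_prob,
    qpcr = qpcr,
    disease_A_label = disease_A_label,
    disease_B_label = disease_B_label)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$overlap_size > min(cfg$disease_A_size, cfg$disease_B_size)) {
    stop("configuration error: overlap_size must not exceed either disease ",
         "set size", call. = FALSE)
  }
  probs <- c(cfg$planted_shared_target_prob, cfg$background_target_prob,
             cfg$source_dropout, cfg$hub_attach_prob,
             cfg$planted_member_frac)
  if (any(probs < 0 | probs >= 1) ||
      cfg$planted_shared_target_prob <= 0 ||
      cfg$background_target_prob <= 0) {
    stop("configuration error: probabilities must lie in (0,1) ",
         "(dropout and attachment may be 0)", call. = FALSE)
  }
  union_size <- cfg$disease_A_size + cfg$disease_B_size - cfg$overlap_size
  if (union_size > cfg$n_genes_universe) {
    stop("configuration error: gene universe smaller than the disease union",
         call. = FALSE)
  }
  if (cfg$n_terms_A > cfg$disease_A_size || cfg$n_terms_B > cfg$disease_B_size) {
    stop("configuration error: more terms than genes for a disease",
         call. = FALSE)
  }
  if (cfg$n_planted_top > cfg$n_mirnas) {
    stop("configuration error: n_planted_top exceeds n_mirnas", call. = FALSE)
  }
  if (length(cfg$library_term_size) != 2L ||
      cfg$library_term_size[2] > cfg$n_genes_universe) {
    stop("configuration error: library term size range invalid or larger ",
         "than the universe", call. = FALSE)
  }
  validate_qpcr_config(cfg$qpcr)
  invisible(cfg)
}

# stable per-generator RNG stream offsets (keep seed + offset < 2^31)
.SIM_STREAMS <- c(associations = 101L, predictions = 202L, gmt = 303L,
                  interactome = 404L, qpcr = 505L)

sim_stream_seed <- function(config, stream) {
  offset <- .SIM_STREAMS[[stream]]
  (config$seed + offset) %% .Machine$integer.max
}
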