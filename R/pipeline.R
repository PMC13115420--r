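# End-to-end orchestration: simulate -> genesets -> rank -> enrich ->
# network -> expression, each stage communicating only through declared
# files under the output directory, with a checksum manifest. Identical
# config + seed gives a byte-identical manifest (wall times go to the log,
# not the manifest, so manifests can be diffed across runs).

#' Construct a pipeline run configuration
#'
#' All thresholds are surfaced; defaults are the emulated study's stated
#' values where it states one (top 10\% decile, top 5 terms, adjusted
#' p < 0.05, top 20 shared / 15 per-miRNA hubs, Ct cutoff 40) and package
#' choices where it does not (min_sources 1, confidence 0.4).
#'
#' @param seed integer master seed for the simulate stage.
#' @param out_dir output directory (created if missing).
#' @param stages named logical: which of simulate, genesets, rank, enrich,
#'   network, expression to run.
#' @param thresholds named list: \code{min_sources}, \code{alpha},
#'   \code{top_k}, \code{decile}, \code{min_confidence},
#'   \code{n_shared_hubs}, \code{n_each_hubs}, \code{ct_cutoff},
#'   \code{background_size} (defaults to the simulated universe size).
#' @param sim named list of \code{\link{sim_config}} overrides.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L,
                       out_dir = tempfile("sharedmiR-run-"),
                       stages = c(simulate = TRUE, genesets = TRUE,
                                  rank = TRUE, enrich = TRUE,
                                  network = TRUE, expression = TRUE),
                       thresholds = list(),
                       sim = list()) {
  default_stages <- c(simulate = TRUE, genesets = TRUE, rank = TRUE,
                      enrich = TRUE, network = TRUE, expression = TRUE)
  default_stages[names(stages)] <- unlist(stages)
  default_thresholds <- list(min_sources = 1L, alpha = 0.05, top_k = 5L,
                             decile = 0.1, min_confidence = 0.4,
                             n_shared_hubs = 20L, n_each_hubs = 15L,
                             ct_cutoff = 40, background_size = NULL)
  default_thresholds[names(thresholds)] <- thresholds
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              stages = default_stages, thresholds = default_thresholds,
              sim = sim)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$min_sources >= 1, th$alpha > 0, th$alpha <= 1,
            th$top_k >= 1, th$decile > 0, th$decile <= 1,
            th$min_confidence >= 0, th$min_confidence <= 1,
            th$n_shared_hubs >= 1, th$n_each_hubs >= 1, th$ct_cutoff > 0)
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file whose keys
#'   mirror the arguments of \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format: .", ext, call. = FALSE))
  run_config(seed = raw$seed %||% 1L,
             out_dir = raw$out_dir %||% tempfile("sharedmiR-run-"),
             stages = unlist(raw$stages) %||% c(simulate = TRUE),
             thresholds = raw$thresholds %||% list(),
             sim = raw$sim %||% list())
}

pipeline_files <- function(out_dir) {
  f <- function(x) file.path(out_dir, x)
  list(associations = f("associations.tsv"),
       predictions = f("predictions.tsv"),
       gmt = f("library.gmt"),
       interactome = f("interactome.tsv"),
       ct = f("qpcr_ct.csv"),
       sim_config = f("sim_config.json"),
       genes_A = f("genes_A.txt"), genes_B = f("genes_B.txt"),
       genes_shared = f("genes_shared.txt"),
       genes_A_only = f("genes_A_only.txt"),
       genes_B_only = f("genes_B_only.txt"),
       genesets_summary = f("genesets_summary.json"),
       ranking = f("ranking.tsv"), top_decile = f("top_decile.tsv"),
       enrichment = f("enrichment.tsv"),
       network_nodes = f("network_nodes.tsv"),
       network_edges = f("network_edges.tsv"),
       relative_expression = f("relative_expression.csv"),
       group_stats_plasma = f("group_stats_plasma.tsv"),
       group_stats_tissue = f("group_stats_tissue.tsv"),
       spike_qc = f("spike_qc.csv"),
       boxplot_stats = f("boxplot_stats.tsv"),
       manifest = f("manifest.json"))
}

# the two highest-ranked miRNAs of the top decile (a single-miRNA decile is
# compared with itself)
top_two_mirnas <- function(decile) {
  ids <- decile$mirna_id
  if (length(ids) == 1L) rep(ids, 2L) else ids[1:2]
}

mirna_targets <- function(pairs, mirna) {
  unique(pairs$gene_id[pairs$mirna_id == mirna])
}

# LSD p-value for an unordered group pair
lsd_pair_p <- function(cmp, g1, g2) {
  pw <- cmp$pairwise
  hit <- (pw$group1 == g1 & pw$group2 == g2) |
    (pw$group1 == g2 & pw$group2 == g1)
  if (!any(hit)) return(NA_real_)
  pw$p[hit][1]
}

#' Run the shared-disease miRNA prioritization pipeline
#'
#' Executes the enabled stages in order (simulate, genesets, rank, enrich,
#' network, expression); every stage reads and writes only declared files
#' under \code{out_dir}. On success a \code{manifest.json} listing each
#' stage's inputs and output md5 checksums is written; identical config +
#' seed yields a byte-identical manifest. A failing stage writes the partial
#' manifest, drops a \code{FAILED} marker naming the stage, and aborts.
#'
#' @param config a \code{\link{run_config}} (or plain list of its fields).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    config <- run_config(seed = config$seed %||% 1L,
                         out_dir = config$out_dir %||%
                           tempfile("sharedmiR-run-"),
                         stages = unlist(config$stages) %||%
                           c(simulate = TRUE),
                         thresholds = config$thresholds %||% list(),
                         sim = config$sim %||% list())
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_files(out_dir)
  th <- config$thresholds
  manifest <- list(pipeline = "sharedmiR",
                   version = as.character(utils::packageVersion("sharedmiR")),
                   seed = config$seed, stages = list())

  record <- function(stage, inputs, outputs) {
    in_files <- as.character(unlist(inputs))
    out_files <- as.character(unlist(outputs))
    manifest$stages[[stage]] <<- list(
      inputs = basename(in_files),
      outputs = stats::setNames(as.list(tools::md5sum(out_files)),
                                basename(out_files)))
  }
  run_stage <- function(stage, fun) {
    if (!isTRUE(config$stages[[stage]])) {
      message(sprintf("[%s] skipped", stage))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e) {
      writeLines(stage, file.path(out_dir, "FAILED"))
      jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                           pretty = TRUE)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))
  }

  sim_label_A <- config$sim$disease_A_label %||% "Parkinson disease"
  sim_label_B <- config$sim$disease_B_label %||% "glioblastoma"

  run_stage("simulate", function() {
    sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    assoc <- generate_disease_associations(sim_cfg)
    write_tsv_plain(assoc, paths$associations)
    shared <- attr(assoc, "shared")
    a_only <- attr(assoc, "A_only")
    b_only <- attr(assoc, "B_only")
    preds <- generate_target_predictions(sim_cfg, shared, a_only, b_only)
    write_tsv_plain(preds, paths$predictions)
    planted <- attr(preds, "planted_mirnas")
    t1 <- intersect(mirna_targets(preds, planted[1]), shared)
    t2 <- intersect(mirna_targets(preds, planted[min(2L, length(planted))]),
                    shared)
    pool <- intersect(t1, t2)
    lib <- generate_gmt_library(sim_cfg, pool)
    write_gmt(lib, paths$gmt)
    # interactome nodes: shared genes targeted by the top planted miRNAs,
    # hub candidates (targets of both) first so the planted hubs sit in the
    # network's shared group
    nodes <- c(sort(pool), sort(setdiff(union(t1, t2), pool)))
    net_edges <- generate_interactome(sim_cfg, nodes)
    write_tsv_plain(net_edges, paths$interactome)
    ct <- generate_qpcr_dataset(sim_cfg)
    utils::write.csv(ct, paths$ct, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(sim_cfg)[setdiff(names(sim_cfg), "qpcr")],
                         paths$sim_config, auto_unbox = TRUE, pretty = TRUE)
    record("simulate", list(),
           paths[c("associations", "predictions", "gmt", "interactome",
                   "ct", "sim_config")])
  })

  run_stage("genesets", function() {
    assoc <- read_associations(paths$associations)
    terms_A <- unique(assoc$term_id[assoc$disease_label == sim_label_A])
    terms_B <- unique(assoc$term_id[assoc$disease_label == sim_label_B])
    set_A <- build_disease_set(assoc, terms_A, sim_label_A)
    set_B <- build_disease_set(assoc, terms_B, sim_label_B)
    sets <- intersect_disease_sets(set_A, set_B)
    message(sprintf("[genesets] |A| = %d, |B| = %d, shared = %d",
                    length(set_A$genes), length(set_B$genes),
                    length(sets$shared)))
    write_gene_set(set_A$genes, paths$genes_A)
    write_gene_set(set_B$genes, paths$genes_B)
    write_gene_set(sets$shared, paths$genes_shared)
    write_gene_set(sets$A_only, paths$genes_A_only)
    write_gene_set(sets$B_only, paths$genes_B_only)
    jsonlite::write_json(list(
      A = list(disease = sim_label_A, n_terms = length(terms_A),
               n_genes = length(set_A$genes)),
      B = list(disease = sim_label_B, n_terms = length(terms_B),
               n_genes = length(set_B$genes)),
      shared = length(sets$shared)),
      paths$genesets_summary, auto_unbox = TRUE, pretty = TRUE)
    record("genesets", paths["associations"],
           paths[c("genes_A", "genes_B", "genes_shared", "genes_A_only",
                   "genes_B_only", "genesets_summary")])
  })

  run_stage("rank", function() {
    preds <- read_tsv_plain(paths$predictions)
    shared <- read_gene_set(paths$genes_shared)
    uni_A <- read_gene_set(paths$genes_A)
    uni_B <- read_gene_set(paths$genes_B)
    pairs <- aggregate_predictions(preds, th$min_sources)
    ranked <- rank_mirnas(mirna_rank_records(pairs, shared, uni_A, uni_B))
    ranked$cluster <- oner_cluster(ranked$n_shared)
    write_tsv_plain(ranked, paths$ranking)
    decile <- select_top_decile(ranked, th$decile)
    write_tsv_plain(decile, paths$top_decile)
    message(sprintf("[rank] %d miRNAs ranked, top decile = %d",
                    nrow(ranked), nrow(decile)))
    record("rank", paths[c("predictions", "genes_shared", "genes_A",
                           "genes_B")],
           paths[c("ranking", "top_decile")])
  })

  run_stage("enrich", function() {
    decile <- read_tsv_plain(paths$top_decile)
    preds <- read_tsv_plain(paths$predictions)
    shared <- read_gene_set(paths$genes_shared)
    lib <- read_gmt(paths$gmt)
    top2 <- top_two_mirnas(decile)
    t_a <- intersect(mirna_targets(preds, top2[1]), shared)
    t_b <- intersect(mirna_targets(preds, top2[2]), shared)
    bg <- th$background_size %||% config$sim$n_genes_universe %||% 20000L
    res <- shared_target_enrichment(t_a, t_b, list(simulated = lib), bg,
                                    top_k = th$top_k, alpha = th$alpha)
    write_tsv_plain(res, paths$enrichment)
    message(sprintf("[enrich] %d significant term(s) reported for %s & %s",
                    nrow(res), top2[1], top2[2]))
    record("enrich", paths[c("top_decile", "predictions", "genes_shared",
                             "gmt")],
           paths["enrichment"])
  })

  run_stage("network", function() {
    decile <- read_tsv_plain(paths$top_decile)
    preds <- read_tsv_plain(paths$predictions)
    shared <- read_gene_set(paths$genes_shared)
    edges <- read_tsv_plain(paths$interactome)
    top2 <- top_two_mirnas(decile)
    net <- build_network(edges, mirna_targets(preds, top2[1]),
                         mirna_targets(preds, top2[2]), shared,
                         min_confidence = th$min_confidence)
    deg <- compute_degrees(net)
    hubs <- select_hubs(net, n_shared = th$n_shared_hubs,
                        n_each = th$n_each_hubs)
    hub_tbl <- dplyr::bind_rows(lapply(names(hubs), function(g) {
      h <- hubs[[g]]
      dplyr::bind_cols(h["gene"], group = g, h[c("degree", "rank")],
                       circular_layout(h$gene)[c("x", "y")])
    }))
    node_tbl <- dplyr::left_join(
      dplyr::mutate(net$nodes, degree = as.integer(deg[.data$gene])),
      hub_tbl[, c("gene", "rank", "x", "y")], by = "gene") |>
      dplyr::arrange(.data$group, dplyr::desc(.data$degree), .data$gene)
    write_tsv_plain(node_tbl, paths$network_nodes)
    write_tsv_plain(net$edges, paths$network_edges)
    message(sprintf("[network] %d nodes, %d edges, hubs %s",
                    nrow(net$nodes), nrow(net$edges),
                    paste(vapply(hubs, nrow, 1L), collapse = "/")))
    record("network", paths[c("top_decile", "predictions", "genes_shared",
                              "interactome")],
           paths[c("network_nodes", "network_edges")])
  })

  run_stage("expression", function() {
    ct <- utils::read.csv(paths$ct, stringsAsFactors = FALSE)
    plasma <- ct[ct$compartment == "plasma", ]
    tissue <- ct[ct$compartment %in% c("tumor", "peritumoral"), ]
    rel_p <- relative_expression_table(plasma, calibrator_group = "control",
                                       group_col = "group",
                                       ct_cutoff = th$ct_cutoff)
    rel_p$context <- "plasma"
    rel <- rel_p
    if (nrow(tissue) > 0L) {
      rel_t <- relative_expression_table(tissue,
                                         calibrator_group = "peritumoral",
                                         group_col = "compartment",
                                         ct_cutoff = th$ct_cutoff)
      rel_t$context <- "tissue"
      rel <- rbind(rel_p, rel_t)
    }
    utils::write.csv(rel, paths$relative_expression, row.names = FALSE,
                     quote = FALSE)

    plasma_stats <- dplyr::bind_rows(lapply(
      sort(unique(rel_p$analyte)), function(a) {
        sub <- rel_p[rel_p$analyte == a, ]
        ok <- tapply(!is.na(sub$ratio), sub$group, sum)
        if (length(ok) < 2L || any(ok < 2L)) {
          message(sprintf("[expression] %s: too few detectable values, ",
                          a), "group stats skipped")
          return(NULL)
        }
        cmp <- anova_lsd(sub$ratio, sub$group)
        fc_pd <- group_fold_change(cmp$means, "glioma", "PD")
        fc_ctrl <- group_fold_change(cmp$means, "glioma", "control")
        tibble::tibble(
          analyte = a,
          mean_control = unname(cmp$means[["control"]]),
          mean_PD = unname(cmp$means[["PD"]]),
          mean_glioma = unname(cmp$means[["glioma"]]),
          F = cmp$F, p_overall = cmp$p_overall,
          p_glioma_vs_control = lsd_pair_p(cmp, "glioma", "control"),
          p_glioma_vs_PD = lsd_pair_p(cmp, "glioma", "PD"),
          fold_glioma_vs_PD = fc_pd$fold,
          fold_glioma_vs_control = fc_ctrl$fold)
      }))
    write_tsv_plain(plasma_stats, paths$group_stats_plasma)

    tissue_stats <- NULL
    if (nrow(tissue) > 0L) {
      rel_t <- rel[rel$context == "tissue", ]
      tissue_stats <- dplyr::bind_rows(lapply(
        sort(unique(rel_t$analyte)), function(a) {
          sub <- rel_t[rel_t$analyte == a, ]
          tv <- sub$ratio[sub$group == "tumor"]
          pv <- sub$ratio[sub$group == "peritumoral"]
          if (sum(!is.na(tv)) < 2L || sum(!is.na(pv)) < 2L) return(NULL)
          tt <- two_sample_t(tv, pv)
          means <- c(tumor = mean(tv, na.rm = TRUE),
                     peritumoral = mean(pv, na.rm = TRUE))
          fc <- group_fold_change(means, "tumor", "peritumoral")
          tibble::tibble(analyte = a, mean_tumor = means[["tumor"]],
                         mean_peritumoral = means[["peritumoral"]],
                         t = tt$t, p = tt$p,
                         fold_tumor_vs_peritumoral = fc$fold)
        }))
    }
    write_tsv_plain(tissue_stats %||%
                      tibble::tibble(analyte = character()),
                    paths$group_stats_tissue)

    spike <- plasma[plasma$analyte == "cel-miR-39-3p", ]
    qc <- if (nrow(spike) > 0L) {
      spike_in_qc(stats::setNames(spike$ct, spike$sample_id))
    } else {
      tibble::tibble(sample_id = character(), ct = numeric(),
                     deviation = numeric(), pass = logical())
    }
    utils::write.csv(qc, paths$spike_qc, row.names = FALSE, quote = FALSE)

    box <- dplyr::bind_rows(lapply(split(
      rel, paste(rel$context, rel$analyte, rel$group)), function(sub) {
        if (all(is.na(sub$ratio))) return(NULL)
        b <- boxplot_summary(sub$ratio)
        tibble::tibble(context = sub$context[1], analyte = sub$analyte[1],
                       group = sub$group[1], n = b$n, mean = b$mean,
                       median = b$median, q1 = b$q1, q3 = b$q3,
                       whisker_low = b$whisker_low,
                       whisker_high = b$whisker_high,
                       n_outliers = length(b$outliers))
      }))
    write_tsv_plain(box, paths$boxplot_stats)
    record("expression", paths["ct"],
           paths[c("relative_expression", "group_stats_plasma",
                   "group_stats_tissue", "spike_qc", "boxplot_stats")])
  })

  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  if (file.exists(file.path(out_dir, "FAILED"))) {
    unlink(file.path(out_dir, "FAILED"))
  }
  invisible(manifest)
}
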