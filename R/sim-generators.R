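# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with planted ground truth (exact set overlap, planted
# high-shared-target miRNAs, planted enriched terms, planted hubs, planted
# log2 effects), so all downstream stages are testable with no database
# access. Each generator draws from its own RNG stream (seed + stable
# offset) and restores the caller's RNG state on exit.

#' Gene identifiers of the simulated universe
#'
#' Stable synthetic gene ids ("G00001", ...) used by every generator; the
#' first \code{n} ids are the universe of a \code{\link{sim_config}} with
#' \code{n_genes_universe = n}.
#'
#' @param n universe size.
#' @export
make_gene_ids <- function(n) {
  sprintf("G%0*d", max(5L, nchar(n)), seq_len(n))
}

gene_symbol_of <- function(gene_id) sub("^G", "SYM", gene_id)

# assign genes to terms so that every term is non-empty and the union over
# terms is exactly `genes`
assign_terms <- function(genes, term_ids) {
  g <- sample(genes)
  extra <- length(g) - length(term_ids)
  terms <- c(term_ids,
             if (extra > 0) sample(term_ids, extra, replace = TRUE))
  data.frame(gene_id = g, term_id = terms, stringsAsFactors = FALSE)
}

#' Generate a gene-disease association table with an exactly planted overlap
#'
#' Emulates a DisGeNET-style export: one row per (gene, term) association
#' with a disease label, a source class (curated / literature) and a score
#' in \code{[0, 1]}. The union of each disease's term-level gene lists has
#' exactly the configured size and the two unions intersect in exactly
#' \code{overlap_size} genes (the overlap is planted, not sampled).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a tibble with columns \code{gene_id}, \code{gene_symbol},
#'   \code{term_id}, \code{disease_label}, \code{source_class},
#'   \code{score}; the planted gene partition is attached as attributes
#'   \code{shared}, \code{A_only}, \code{B_only}.
#' @export
generate_disease_associations <- function(config) {
  validate_sim_config(config)
  local_seed(sim_stream_seed(config, "associations"), {
    universe <- make_gene_ids(config$n_genes_universe)
    union_size <- config$disease_A_size + config$disease_B_size -
      config$overlap_size
    picked <- sample(universe, union_size)
    shared <- sort(picked[seq_len(config$overlap_size)])
    a_only <- sort(picked[config$overlap_size +
                            seq_len(config$disease_A_size -
                                      config$overlap_size)])
    b_only <- sort(picked[config$disease_A_size +
                            seq_len(config$disease_B_size -
                                      config$overlap_size)])

    terms_A <- sprintf("A_TERM_%02d", seq_len(config$n_terms_A))
    terms_B <- sprintf("B_TERM_%02d", seq_len(config$n_terms_B))
    rows_A <- assign_terms(c(shared, a_only), terms_A)
    rows_A$disease_label <- config$disease_A_label
    rows_B <- assign_terms(c(shared, b_only), terms_B)
    rows_B$disease_label <- config$disease_B_label

    out <- rbind(rows_A, rows_B)
    out$gene_symbol <- gene_symbol_of(out$gene_id)
    out$source_class <- sample(c("curated", "literature"), nrow(out),
                               replace = TRUE)
    out$score <- round(stats::runif(nrow(out)), 4)
    out <- out[order(out$disease_label, out$term_id, out$gene_id), ]
    out <- tibble::as_tibble(out[, c("gene_id", "gene_symbol", "term_id",
                                     "disease_label", "source_class",
                                     "score")])
    attr(out, "shared") <- shared
    attr(out, "A_only") <- a_only
    attr(out, "B_only") <- b_only
    out
  })
}

#' Generate a multi-source miRNA-target prediction table
#'
#' Planted-top miRNAs target each shared gene with
#' \code{planted_shared_target_prob}; all other (miRNA, gene-set) pairs use
#' \code{background_target_prob}. Each predicted pair is independently
#' attributed to each of the \code{n_sources} source databases with
#' probability \code{1 - source_dropout}; a pair that would lose all sources
#' keeps one source drawn uniformly, so every emitted pair appears in at
#' least one source.
#'
#' @param config a \code{\link{sim_config}}.
#' @param shared_genes,A_only,B_only disjoint gene-id vectors (the planted
#'   partition).
#' @return a tibble with columns \code{mirna_id}, \code{gene_id},
#'   \code{gene_symbol}, \code{source_db}, \code{score}; planted miRNA ids
#'   are attached as attribute \code{planted_mirnas}.
#' @export
generate_target_predictions <- function(config, shared_genes, A_only,
                                        B_only) {
  if (length(shared_genes) == 0L || length(A_only) == 0L ||
      length(B_only) == 0L) {
    stop("empty gene set: shared, A-only and B-only sets must all be ",
         "non-empty", call. = FALSE)
  }
  stopifnot(length(intersect(shared_genes, A_only)) == 0L,
            length(intersect(shared_genes, B_only)) == 0L,
            length(intersect(A_only, B_only)) == 0L)
  local_seed(sim_stream_seed(config, "predictions"), {
    m <- config$n_mirnas
    mirnas <- sprintf("hsa-miR-s%03d-5p", seq_len(m))
    planted <- mirnas[seq_len(config$n_planted_top)]
    p_shared <- rep(config$background_target_prob, m)
    p_shared[seq_len(config$n_planted_top)] <- config$planted_shared_target_prob

    draw_pairs <- function(genes, probs) {
      hit <- matrix(stats::runif(m * length(genes)), nrow = m) < probs
      idx <- which(hit, arr.ind = TRUE)
      data.frame(mirna_id = mirnas[idx[, 1L]],
                 gene_id = genes[idx[, 2L]],
                 stringsAsFactors = FALSE)
    }
    bg <- rep(config$background_target_prob, m)
    pairs <- rbind(draw_pairs(shared_genes, p_shared),
                   draw_pairs(A_only, bg),
                   draw_pairs(B_only, bg))

    np <- nrow(pairs)
    keep <- matrix(stats::runif(np * config$n_sources), nrow = np) <
      (1 - config$source_dropout)
    none <- which(rowSums(keep) == 0L)
    if (length(none) > 0L) {
      keep[cbind(none, sample.int(config$n_sources, length(none),
                                  replace = TRUE))] <- TRUE
    }
    hit <- which(keep, arr.ind = TRUE)
    out <- data.frame(
      mirna_id = pairs$mirna_id[hit[, 1L]],
      gene_id = pairs$gene_id[hit[, 1L]],
      source_db = sprintf("srcdb_%02d", hit[, 2L]),
      score = round(stats::runif(nrow(hit)), 4),
      stringsAsFactors = FALSE)
    out$gene_symbol <- gene_symbol_of(out$gene_id)
    out <- out[order(out$mirna_id, out$gene_id, out$source_db), ]
    out <- tibble::as_tibble(out[, c("mirna_id", "gene_id", "gene_symbol",
                                     "source_db", "score")])
    attr(out, "planted_mirnas") <- planted
    out
  })
}

#' Generate a GMT gene-set library with planted enriched terms
#'
#' Planted terms draw at least \code{planted_member_frac} of their members
#' from \code{planted_gene_pool}; background terms draw uniformly from the
#' universe. Term sizes are sampled from the configured inclusive range.
#'
#' @param config a \code{\link{sim_config}}.
#' @param planted_gene_pool non-empty gene-id vector the planted terms are
#'   enriched for (typically the query set a test will use).
#' @param universe gene-id universe; defaults to the configured simulated
#'   universe.
#' @return named list term -> gene-id vector, with planted term names in
#'   attribute \code{planted_terms}.
#' @export
generate_gmt_library <- function(config, planted_gene_pool,
                                 universe = make_gene_ids(config$n_genes_universe)) {
  if (length(planted_gene_pool) == 0L) {
    stop("planted gene pool must be non-empty", call. = FALSE)
  }
  lo <- config$library_term_size[1]
  hi <- config$library_term_size[2]
  if (hi > length(universe)) {
    stop("term size exceeds the gene universe", call. = FALSE)
  }
  local_seed(sim_stream_seed(config, "gmt"), {
    n_planted <- config$planted_enriched_terms
    n_bg <- config$n_library_terms - n_planted
    sizes <- sample(seq.int(lo, hi), config$n_library_terms, replace = TRUE)
    lib <- vector("list", config$n_library_terms)
    names(lib) <- c(sprintf("PLANTED_TERM_%02d", seq_len(n_planted)),
                    if (n_bg > 0) sprintf("TERM_%03d", seq_len(n_bg)))
    pool <- unique(planted_gene_pool)
    for (i in seq_len(n_planted)) {
      n_from_pool <- min(ceiling(config$planted_member_frac * sizes[i]),
                         length(pool))
      members <- sample(pool, n_from_pool)
      rest <- sizes[i] - n_from_pool
      if (rest > 0) {
        members <- c(members, sample(setdiff(universe, members), rest))
      }
      lib[[i]] <- sort(members)
    }
    for (i in seq.int(n_planted + 1L, length.out = n_bg)) {
      lib[[i]] <- sort(sample(universe, sizes[i]))
    }
    attr(lib, "planted_terms") <- names(lib)[seq_len(n_planted)]
    lib
  })
}

#' Generate a scored interactome edge list with planted hubs
#'
#' Under the preferential-attachment model the planted hubs form the initial
#' clique and every incoming node attaches \code{pa_edges_per_node} edges
#' preferentially (probability proportional to degree + 1) plus an
#' independent extra edge to each planted hub with probability
#' \code{hub_attach_prob}, so the planted hubs carry the highest expected
#' degrees by construction. The configuration model realizes a prescribed
#' degree sequence via \code{igraph::sample_degseq}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param nodes character vector of gene ids; the first
#'   \code{n_planted_hubs} become the planted hubs.
#' @param degree_sequence integer degree per node, required for the
#'   configuration model.
#' @return a tibble with columns \code{gene_a}, \code{gene_b},
#'   \code{confidence} (undirected simple graph, \code{gene_a < gene_b});
#'   planted hub ids in attribute \code{planted_hubs} (empty for the
#'   configuration model).
#' @export
generate_interactome <- function(config, nodes, degree_sequence = NULL) {
  n <- length(nodes)
  if (config$network_model == "preferential_attachment" &&
      n < max(2L, config$n_planted_hubs)) {
    stop("fewer nodes than planted hubs", call. = FALSE)
  }
  local_seed(sim_stream_seed(config, "interactome"), {
    if (config$network_model == "configuration") {
      if (is.null(degree_sequence) || length(degree_sequence) != n) {
        stop("configuration model requires one prescribed degree per node",
             call. = FALSE)
      }
      g <- igraph::sample_degseq(degree_sequence, method = "vl")
      el <- igraph::as_edgelist(g, names = FALSE)
      edges <- data.frame(gene_a = nodes[el[, 1L]], gene_b = nodes[el[, 2L]],
                          stringsAsFactors = FALSE)
      hubs <- character()
    } else {
      m0 <- max(2L, config$n_planted_hubs)
      hubs_idx <- seq_len(config$n_planted_hubs)
      deg <- integer(n)
      ea <- integer(0)
      eb <- integer(0)
      core <- utils::combn(seq_len(m0), 2L)
      ea <- core[1L, ]
      eb <- core[2L, ]
      deg[seq_len(m0)] <- m0 - 1L
      for (i in seq.int(m0 + 1L, length.out = n - m0)) {
        prev <- seq_len(i - 1L)
        m <- min(config$pa_edges_per_node, i - 1L)
        nb <- sample(prev, m, prob = deg[prev] + 1)
        boost <- hubs_idx[stats::runif(length(hubs_idx)) <
                            config$hub_attach_prob]
        nb <- unique(c(nb, boost))
        ea <- c(ea, rep.int(i, length(nb)))
        eb <- c(eb, nb)
        deg[nb] <- deg[nb] + 1L
        deg[i] <- length(nb)
      }
      edges <- data.frame(gene_a = nodes[pmin(ea, eb)],
                          gene_b = nodes[pmax(ea, eb)],
                          stringsAsFactors = FALSE)
      hubs <- nodes[hubs_idx]
    }
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    edges$gene_a <- a
    edges$gene_b <- b
    edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]) &
                     edges$gene_a != edges$gene_b, ]
    edges$confidence <- round(stats::runif(nrow(edges)), 4)
    edges <- edges[order(edges$gene_a, edges$gene_b), ]
    out <- tibble::as_tibble(edges)
    attr(out, "planted_hubs") <- hubs
    out
  })
}

#' Generate an RT-qPCR Ct table with planted log2 effects
#'
#' Emits three plasma groups (control, PD, glioma) plus paired
#' tumor/peritumoral tissue samples. For a target analyte with efficiency E
#' and a planted log2 effect L relative to the calibrator group, Ct is drawn
#' as \code{baseline - L / log2(E) + N(0, sd_ct)}, so efficiency-adjusted
#' relative quantification recovers the planted fold change \code{2^L}.
#' Reference (U6) and spike-in (cel-miR-39-3p) rows carry their own small
#' SDs; analytes listed in \code{undetectable_plasma} are planted with
#' Ct > 40 in plasma.
#'
#' @param config a \code{\link{sim_config}}.
#' @return tibble with columns \code{sample_id}, \code{group},
#'   \code{compartment}, \code{analyte}, \code{ct}, \code{efficiency}.
#' @export
generate_qpcr_dataset <- function(config) {
  q <- config$qpcr
  validate_qpcr_config(q)
  local_seed(sim_stream_seed(config, "qpcr"), {
    rows <- list()
    add <- function(sample_id, group, compartment, analyte, ct, efficiency) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, group = group, compartment = compartment,
        analyte = analyte, ct = round(ct, 3), efficiency = efficiency,
        stringsAsFactors = FALSE)
    }
    groups <- c("control", "PD", "glioma")
    n <- q$n_per_group
    plasma_ids <- lapply(groups, function(g) sprintf("PL_%s_%02d", g,
                                                     seq_len(n)))
    names(plasma_ids) <- groups

    for (a in q$analytes_plasma) {
      E <- analyte_efficiency(q, a)
      eff <- q$plasma_log2_effects[[a]]
      for (g in groups) {
        if (a %in% q$undetectable_plasma) {
          ct <- stats::runif(n, 41, 44)
        } else {
          L <- if (!is.null(eff) && g %in% names(eff)) eff[[g]] else 0
          ct <- q$baseline_ct[["target"]] - L / log2(E) +
            stats::rnorm(n, 0, q$sd_ct)
        }
        add(plasma_ids[[g]], g, "plasma", a, ct, E)
      }
    }
    for (g in groups) {
      add(plasma_ids[[g]], g, "plasma", q$reference_analyte,
          q$baseline_ct[["reference"]] + stats::rnorm(n, 0, q$reference_sd),
          2.0)
      add(plasma_ids[[g]], g, "plasma", q$spike_analyte,
          q$baseline_ct[["spike"]] + stats::rnorm(n, 0, q$spike_sd), 2.0)
    }

    tissue_ids <- sprintf("TS_%02d", seq_len(q$n_tissue))
    for (a in q$analytes_tissue) {
      E <- analyte_efficiency(q, a)
      eff <- q$tissue_log2_effects[[a]]
      for (comp in c("peritumoral", "tumor")) {
        L <- if (!is.null(eff) && comp %in% names(eff)) eff[[comp]] else 0
        ct <- q$baseline_ct[["target"]] - L / log2(E) +
          stats::rnorm(q$n_tissue, 0, q$sd_ct)
        add(tissue_ids, "glioma", comp, a, ct, E)
      }
    }
    for (comp in c("peritumoral", "tumor")) {
      add(tissue_ids, "glioma", comp, q$reference_analyte,
          q$baseline_ct[["reference"]] +
            stats::rnorm(q$n_tissue, 0, q$reference_sd), 2.0)
    }
    tibble::as_tibble(do.call(rbind, rows))
  })
}
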