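# miRNA prioritization: aggregate multi-source target predictions, count
# per-miRNA targets in the shared and per-disease gene universes, rank by
# shared-target count, keep the top decile, annotate pathway targets and
# assign four ordered OneR-style clusters.

#' Aggregate multi-source predictions into deduplicated miRNA-gene pairs
#'
#' Union semantics by default (\code{min_sources = 1}): a pair is kept if it
#' is reported by at least \code{min_sources} distinct source databases; the
#' distinct-source count is attached.
#'
#' @param predictions tibble with columns \code{mirna_id}, \code{gene_id},
#'   \code{source_db}.
#' @param min_sources minimum number of distinct sources (>= 1).
#' @return tibble \code{mirna_id}, \code{gene_id}, \code{n_sources}.
#' @export
aggregate_predictions <- function(predictions, min_sources = 1L) {
  stopifnot(min_sources >= 1L)
  require_columns(predictions, c("mirna_id", "gene_id", "source_db"),
                  "prediction table")
  predictions |>
    dplyr::distinct(.data$mirna_id, .data$gene_id, .data$source_db) |>
    dplyr::count(.data$mirna_id, .data$gene_id, name = "n_sources") |>
    dplyr::filter(.data$n_sources >= min_sources) |>
    dplyr::arrange(.data$mirna_id, .data$gene_id)
}

#' Count each miRNA's predicted targets inside a gene set
#'
#' @param pairs deduplicated pair tibble (\code{mirna_id}, \code{gene_id}).
#' @param gene_set non-empty character vector of gene ids to count against.
#' @return named integer vector (one entry per miRNA present in
#'   \code{pairs}, zeros included).
#' @export
count_targets <- function(pairs, gene_set) {
  stopifnot(length(gene_set) > 0L)
  mirnas <- sort(unique(pairs$mirna_id))
  hit <- pairs[pairs$gene_id %in% gene_set, c("mirna_id", "gene_id")]
  hit <- unique(hit)
  counts <- table(factor(hit$mirna_id, levels = mirnas))
  stats::setNames(as.integer(counts), mirnas)
}

#' Build per-miRNA target-count records
#'
#' Counts each miRNA's targets in the shared gene set and against the two
#' whole per-disease gene universes (not the exclusive sets) - the
#' table-compatible counting in which a miRNA's disease count can exceed the
#' size of the exclusive set.
#'
#' @param pairs deduplicated pair tibble.
#' @param shared shared gene set.
#' @param universe_A,universe_B full per-disease gene universes.
#' @return tibble \code{mirna_id}, \code{n_shared}, \code{n_B}, \code{n_A}.
#' @export
mirna_rank_records <- function(pairs, shared, universe_A, universe_B) {
  tibble::tibble(
    mirna_id = sort(unique(pairs$mirna_id)),
    n_shared = count_targets(pairs, shared),
    n_B = count_targets(pairs, universe_B),
    n_A = count_targets(pairs, universe_A))
}

#' Rank miRNAs by shared-target count
#'
#' Descending by \code{n_shared}; ties broken by \code{n_B} descending,
#' \code{n_A} descending, then \code{mirna_id} ascending. Ranks 1..M.
#'
#' @param records tibble with \code{mirna_id}, \code{n_shared} and
#'   optionally \code{n_B}, \code{n_A}.
#' @return the records sorted, with a \code{rank} column.
#' @export
rank_mirnas <- function(records) {
  stopifnot(nrow(records) >= 1L)
  if (!"n_B" %in% names(records)) records$n_B <- 0L
  if (!"n_A" %in% names(records)) records$n_A <- 0L
  records |>
    dplyr::arrange(dplyr::desc(.data$n_shared), dplyr::desc(.data$n_B),
                   dplyr::desc(.data$n_A), .data$mirna_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Keep the top decile of a ranking
#'
#' @param ranked output of \code{\link{rank_mirnas}}.
#' @param fraction fraction kept; the first \code{ceiling(fraction * M)}
#'   records are returned.
#' @export
select_top_decile <- function(ranked, fraction = 0.1) {
  stopifnot(nrow(ranked) >= 1L, fraction > 0, fraction <= 1)
  dplyr::slice_head(ranked, n = as.integer(ceiling(fraction * nrow(ranked))))
}

#' Annotate each miRNA's targets within named pathway gene lists
#'
#' For every (miRNA, pathway) pair, reports the sorted symbols of the
#' miRNA's predicted targets that fall inside the pathway list, joined with
#' \code{"|"}, plus the count. Pathway genes absent from the predictions are
#' simply never hit.
#'
#' @param pairs pair tibble with \code{mirna_id} and a symbol column.
#' @param pathway_lists non-empty named list: pathway name -> gene symbols.
#' @param symbol_col column of \code{pairs} holding the symbols matched
#'   against pathway lists.
#' @return tibble \code{mirna_id}, \code{pathway}, \code{genes} (pipe
#'   joined, "" when empty), \code{n}.
#' @export
annotate_pathways <- function(pairs, pathway_lists,
                              symbol_col = "gene_symbol") {
  stopifnot(length(pathway_lists) > 0L, !is.null(names(pathway_lists)))
  require_columns(pairs, c("mirna_id", symbol_col), "pair table")
  targets <- split(pairs[[symbol_col]], pairs$mirna_id)
  out <- lapply(names(targets), function(m) {
    tg <- unique(targets[[m]])
    hits <- lapply(pathway_lists, function(pw) sort(intersect(tg, pw)))
    tibble::tibble(mirna_id = m, pathway = names(pathway_lists),
                   genes = unname(vapply(hits, paste, "", collapse = "|")),
                   n = unname(lengths(hits)))
  })
  dplyr::bind_rows(out)
}

#' Assign ordered equal-frequency clusters on the shared-target count
#'
#' OneR-style discretization into \code{n_clusters} ordered bins of the
#' shared-target count: cluster 1 holds the highest counts, bins are
#' equal-frequency, and tied counts always share the cluster of their first
#' (highest-ranked) occurrence, so counts are non-increasing across cluster
#' boundaries.
#'
#' @param n_shared numeric vector of shared-target counts (any order).
#' @param n_clusters number of ordered bins (default 4).
#' @return integer cluster labels aligned with the input order.
#' @export
oner_cluster <- function(n_shared, n_clusters = 4L) {
  m <- length(n_shared)
  if (m < n_clusters) {
    stop("need at least as many records as clusters", call. = FALSE)
  }
  ord <- order(-n_shared)
  sorted <- n_shared[ord]
  provisional <- as.integer(ceiling(n_clusters * seq_len(m) / m))
  # tied values inherit the bin of their first occurrence
  sorted_cluster <- provisional[match(sorted, sorted)]
  if (length(unique(sorted_cluster)) < n_clusters) {
    message("oner_cluster: ties leave ",
            n_clusters - length(unique(sorted_cluster)),
            " cluster(s) empty")
  }
  out <- integer(m)
  out[ord] <- sorted_cluster
  out
}
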