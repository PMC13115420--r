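# Per-disease gene sets from association tables and shared/exclusive set
# arithmetic. gene_id is the primary identifier throughout; symbols are
# annotation only.

#' Read a gene-disease association table
#'
#' Reads a DisGeNET-style TSV (columns \code{gene_id}, \code{gene_symbol},
#' \code{term_id}, \code{disease_label}, \code{source_class}, \code{score}),
#' keeps rows whose source class is in the allowlist and whose score reaches
#' the minimum, and collapses duplicate (gene, term) rows within a disease
#' keeping the maximum score.
#'
#' @param path path to the TSV file.
#' @param source_classes allowed source classes; default mirrors the curated
#'   + literature provenance filter.
#' @param min_score minimum association score kept (default 0: provenance
#'   filter only).
#' @return tibble of associations; zero rows (with a warning) if nothing
#'   passes the filters.
#' @export
read_associations <- function(path,
                              source_classes = c("curated", "literature"),
                              min_score = 0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read_tsv_plain(path)
  require_columns(df, c("gene_id", "term_id", "disease_label",
                        "source_class", "score"),
                  what = "association table")
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- df$gene_id
  n_raw <- nrow(df)
  df <- df[df$source_class %in% source_classes & df$score >= min_score, ]
  df <- df |>
    dplyr::group_by(.data$disease_label, .data$term_id, .data$gene_id) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$disease_label, .data$term_id, .data$gene_id)
  message(sprintf("read_associations: %d rows read, %d kept after filters",
                  n_raw, nrow(df)))
  if (nrow(df) == 0L) warning("no associations left after filtering")
  tibble::as_tibble(df)
}

#' Build a disease gene set as the union over requested terms
#'
#' @param assocs association tibble (see \code{\link{read_associations}}).
#' @param term_ids non-empty character vector of term ids to union over.
#' @param disease_label optional label recorded on the result.
#' @return object of class \code{disease_gene_set} with sorted unique
#'   \code{genes}.
#' @export
build_disease_set <- function(assocs, term_ids, disease_label = NULL) {
  stopifnot(length(term_ids) > 0L)
  known <- unique(assocs$term_id)
  unknown <- setdiff(term_ids, known)
  if (length(unknown) == length(term_ids)) {
    stop("none of the requested term ids are present: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(unknown) > 0L) {
    warning("unknown term id(s) ignored: ", paste(unknown, collapse = ", "))
  }
  hit <- assocs[assocs$term_id %in% term_ids, ]
  structure(list(
    disease_label = disease_label %||% unique(hit$disease_label)[1],
    term_ids = sort(intersect(term_ids, known)),
    genes = sort(unique(hit$gene_id)),
    provenance_filter = attr(assocs, "provenance_filter")),
    class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  cat("<disease_gene_set>", x$disease_label, "-", length(x$term_ids),
      "terms,", length(x$genes), "genes\n")
  invisible(x)
}

#' Intersect two disease gene sets
#'
#' Partitions the union of two disease gene sets into the shared set
#' (intersection) and the two exclusive sets (set differences).
#'
#' @param A,B \code{disease_gene_set} objects built in the same identifier
#'   namespace.
#' @return object of class \code{shared_gene_sets} with sorted fields
#'   \code{shared}, \code{A_only}, \code{B_only}.
#' @export
intersect_disease_sets <- function(A, B) {
  stopifnot(inherits(A, "disease_gene_set"), inherits(B, "disease_gene_set"))
  if (length(A$genes) == 0L || length(B$genes) == 0L) {
    stop("cannot intersect an empty disease gene set", call. = FALSE)
  }
  structure(list(
    shared = sort(intersect(A$genes, B$genes)),
    A_only = sort(setdiff(A$genes, B$genes)),
    B_only = sort(setdiff(B$genes, A$genes)),
    A_label = A$disease_label, B_label = B$disease_label),
    class = "shared_gene_sets")
}

#' @export
print.shared_gene_sets <- function(x, ...) {
  cat(sprintf("<shared_gene_sets> shared %d | %s-only %d | %s-only %d\n",
              length(x$shared), x$A_label, length(x$A_only), x$B_label,
              length(x$B_only)))
  invisible(x)
}

#' Write a gene set as one-gene-per-line text
#' @param genes character vector of gene ids.
#' @param path output path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(sort(unique(genes)), path)
  invisible(path)
}

#' Read a one-gene-per-line gene-set file
#' @param path input path.
#' @export
read_gene_set <- function(path) {
  sort(unique(readLines(path)))
}
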