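# Target-target interaction network restricted to shared disease genes:
# nodes grouped by regulating miRNA (A-only / shared / B-only), confidence
# filtered scored edges, degree-ranked hubs, degree-sorted circular layout.

#' Build the miRNA-target interaction network on shared disease genes
#'
#' Node set = (targets of miRNA A union targets of miRNA B) intersected with
#' the shared gene list; each node is grouped as \code{A_only},
#' \code{shared} or \code{B_only} by which miRNA(s) target it. Edges are
#' kept when both endpoints are nodes and the confidence reaches the
#' threshold; self-loops and duplicate unordered pairs are dropped (maximum
#' confidence retained).
#'
#' @param edges tibble with \code{gene_a}, \code{gene_b}, \code{confidence}
#'   in \code{[0, 1]}.
#' @param targets_A,targets_B target gene sets of the two miRNAs.
#' @param shared_gene_list the shared disease gene set.
#' @param min_confidence STRING-style confidence threshold (default 0.4).
#' @return object of class \code{interaction_network}: list with
#'   \code{nodes} (tibble \code{gene}, \code{group}) and \code{edges}.
#' @export
build_network <- function(edges, targets_A, targets_B, shared_gene_list,
                          min_confidence = 0.4) {
  require_columns(edges, c("gene_a", "gene_b", "confidence"), "edge list")
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]", call. = FALSE)
  }
  nodes <- intersect(union(targets_A, targets_B), shared_gene_list)
  if (length(nodes) == 0L) {
    stop("empty node set: no shared genes are targeted", call. = FALSE)
  }
  in_a <- nodes %in% targets_A
  in_b <- nodes %in% targets_B
  group <- ifelse(in_a & in_b, "shared", ifelse(in_a, "A_only", "B_only"))
  node_tbl <- tibble::tibble(gene = nodes, group = group) |>
    dplyr::arrange(.data$gene)

  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  e <- tibble::tibble(gene_a = a, gene_b = b,
                      confidence = edges$confidence)
  e <- e[e$gene_a != e$gene_b &
           e$gene_a %in% nodes & e$gene_b %in% nodes &
           e$confidence >= min_confidence, ]
  # keep the best-scored record of each unordered pair
  e <- e[order(e$gene_a, e$gene_b, -e$confidence), ]
  e <- e[!duplicated(e[c("gene_a", "gene_b")]), ]

  structure(list(nodes = node_tbl, edges = e,
                 min_confidence = min_confidence),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes (%s), %d edges (conf >= %g)\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(table(x$nodes$group)),
                            table(x$nodes$group)), collapse = ", "),
              nrow(x$edges), x$min_confidence))
  invisible(x)
}

#' Node degrees of an interaction network
#'
#' Degree = number of incident retained edges. Cross-group edges count by
#' default (connectivity is assessed before the per-group display hides
#' them); set \code{drop_cross_group = TRUE} to restrict degrees to
#' within-group edges.
#'
#' @param network an \code{interaction_network}.
#' @param drop_cross_group drop edges whose endpoints lie in different
#'   groups before counting.
#' @return named integer vector over all nodes (zeros included).
#' @export
compute_degrees <- function(network, drop_cross_group = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  if (drop_cross_group) {
    grp <- stats::setNames(network$nodes$group, network$nodes$gene)
    e <- e[grp[e$gene_a] == grp[e$gene_b], ]
  }
  counts <- table(factor(c(e$gene_a, e$gene_b),
                         levels = network$nodes$gene))
  stats::setNames(as.integer(counts), network$nodes$gene)
}

#' Select per-group hub genes by degree
#'
#' Within each node group, the top genes by (degree descending, gene id
#' ascending): \code{n_shared} for the shared group and \code{n_each} for
#' each exclusive group. If a group has fewer genes, all are returned with a
#' note.
#'
#' @param network an \code{interaction_network}.
#' @param n_shared,n_each hub list sizes (defaults 20 and 15).
#' @param drop_cross_group see \code{\link{compute_degrees}}.
#' @return named list (\code{A_only}, \code{shared}, \code{B_only}) of
#'   tibbles \code{gene}, \code{degree}, \code{rank}.
#' @export
select_hubs <- function(network, n_shared = 20L, n_each = 15L,
                        drop_cross_group = FALSE) {
  deg <- compute_degrees(network, drop_cross_group = drop_cross_group)
  sizes <- c(A_only = n_each, shared = n_shared, B_only = n_each)
  out <- lapply(names(sizes), function(g) {
    genes <- network$nodes$gene[network$nodes$group == g]
    d <- deg[genes]
    ord <- order(-d, genes)
    n <- min(sizes[[g]], length(genes))
    if (length(genes) < sizes[[g]]) {
      message(sprintf("select_hubs: group %s has only %d gene(s) (< %d)",
                      g, length(genes), sizes[[g]]))
    }
    tibble::tibble(gene = genes[ord][seq_len(n)],
                   degree = as.integer(d[ord][seq_len(n)]),
                   rank = seq_len(n))
  })
  stats::setNames(out, names(sizes))
}

#' Degree-sorted circular layout
#'
#' Places genes clockwise on the unit circle starting at angle 0, evenly
#' spaced, in the order given (rank order for hub lists).
#'
#' @param genes character vector in display order.
#' @return tibble \code{gene}, \code{x}, \code{y}.
#' @export
circular_layout <- function(genes) {
  n <- length(genes)
  stopifnot(n >= 1L)
  theta <- -2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(gene = genes, x = cos(theta), y = sin(theta))
}
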