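# Hypergeometric over-representation analysis against GMT libraries with
# Benjamini-Hochberg correction. One-sided over-representation only (the
# upper-tail hypergeometric, equivalent to one-sided Fisher's exact).

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the
#' probability of at least \code{k} overlap genes between a query of size
#' \code{n} and a term of size \code{K} drawn from a background of \code{N}
#' genes. Evaluated through \code{stats::phyper}, whose tail computation is
#' numerically stable; returns exactly 1 when \code{k = 0}. Vectorized.
#'
#' @param k observed overlap, \code{0 <= k <= min(K, n)}.
#' @param K term size.
#' @param n query size.
#' @param N background universe size.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop("invalid hypergeometric arguments: need 0 <= k <= min(K, n) and ",
         "K, n <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment (\code{p.adjust(method = "BH")}):
#' \eqn{p_{adj(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1, returned
#' in the input order.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric enrichment of a query gene set against a library
#'
#' Tests every library term, adjusts across all terms of the library
#' (one BH family per library), assigns ranks 1..T by ascending
#' (\code{p_adj}, \code{p}, term name), then keeps terms with
#' \code{p_adj < alpha} truncated to the \code{top_k} best ranks.
#'
#' @param query_genes non-empty character vector of query gene ids.
#' @param library named list: term -> gene-id vector.
#' @param background_size background universe size N (the "human genome"
#'   constant of a real analysis; the fixture universe size in tests).
#' @param top_k maximum number of reported terms (default 5).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return tibble \code{term}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p}, \code{p_adj}, \code{rank}, \code{overlap_genes} (pipe
#'   joined).
#' @export
enrich <- function(query_genes, library, background_size, top_k = 5L,
                   alpha = 0.05) {
  if (length(query_genes) == 0L) stop("query gene set is empty",
                                      call. = FALSE)
  if (length(library) == 0L || is.null(names(library))) {
    stop("library must be a non-empty named list of terms", call. = FALSE)
  }
  query <- unique(query_genes)
  n <- length(query)
  sizes <- lengths(lapply(library, unique))
  if (any(sizes > background_size) || n > background_size) {
    stop("term or query larger than the background universe", call. = FALSE)
  }
  overlap <- lapply(library, function(g) sort(intersect(query, unique(g))))
  k <- lengths(overlap)
  p <- hypergeom_upper_tail(k, sizes, n, background_size)
  p_adj <- bh_adjust(p)
  res <- tibble::tibble(
    term = names(library), k = unname(as.integer(k)),
    K = unname(as.integer(sizes)),
    n = as.integer(n), N = as.integer(background_size),
    p = unname(p), p_adj = unname(p_adj),
    overlap_genes = unname(vapply(overlap, paste, "", collapse = "|")))
  res <- res[order(res$p_adj, res$p, res$term), ]
  res$rank <- seq_len(nrow(res))
  res <- res[res$p_adj < alpha, ]
  utils::head(res[, c("term", "k", "K", "n", "N", "p", "p_adj", "rank",
                      "overlap_genes")], top_k)
}

#' Enrichment of the targets shared by two miRNAs, across libraries
#'
#' Runs \code{\link{enrich}} on the intersection of two target sets against
#' each library and binds the per-library results into one long table.
#'
#' @param targets_A,targets_B non-empty target gene sets of the two miRNAs.
#' @param libraries named list of libraries (each a named list of terms).
#' @param background_size background universe size.
#' @param ... passed to \code{\link{enrich}} (\code{top_k}, \code{alpha}).
#' @return tibble with a \code{library} column prepended; zero rows (with a
#'   warning) when the target intersection is empty.
#' @export
shared_target_enrichment <- function(targets_A, targets_B, libraries,
                                     background_size, ...) {
  stopifnot(length(targets_A) > 0L, length(targets_B) > 0L,
            length(libraries) > 0L, !is.null(names(libraries)))
  common <- intersect(targets_A, targets_B)
  if (length(common) == 0L) {
    warning("no targets shared between the two miRNAs; empty result")
    return(tibble::tibble(library = character(), term = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), p_adj = numeric(),
                          rank = integer(), overlap_genes = character()))
  }
  out <- lapply(names(libraries), function(nm) {
    res <- enrich(common, libraries[[nm]], background_size, ...)
    if (nrow(res) > 0L) res$library <- nm
    res
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0L) {
    res <- res[, c("library", "term", "k", "K", "n", "N", "p", "p_adj",
                   "rank", "overlap_genes")]
  }
  res
}

#' Read a GMT gene-set library
#'
#' @param path path to a tab-separated GMT file.
#' @return named list term -> gene vector.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a named list of gene sets as GMT
#'
#' @param library named list term -> gene vector.
#' @param path output path.
#' @param descriptions optional per-term description column (defaults to the
#'   term name).
#' @export
write_gmt <- function(library, path, descriptions = names(library)) {
  lines <- vapply(seq_along(library), function(i) {
    paste(c(names(library)[i], descriptions[i], library[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
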