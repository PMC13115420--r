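# independent brute-force oracles, kept free of the package's own code paths

# upper-tail hypergeometric by direct pmf summation with exact log
# binomial coefficients
hyper_upper_oracle <- function(k, K, n, N) {
  js <- seq.int(k, min(K, n))
  if (length(js) == 0L) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# hand-written BH step-up: sort ascending, running minimum of m*p/i from the
# top, capped at 1, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- m * p[o] / seq_len(m)
  adj <- rev(cummin(rev(pmin(scaled, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# element-by-element set partition
intersect_oracle <- function(a, b) {
  u <- unique(c(a, b))
  shared <- a_only <- b_only <- character()
  for (g in u) {
    ina <- g %in% a
    inb <- g %in% b
    if (ina && inb) shared <- c(shared, g)
    else if (ina) a_only <- c(a_only, g)
    else if (inb) b_only <- c(b_only, g)
  }
  list(shared = sort(shared), A_only = sort(a_only), B_only = sort(b_only))
}

# adjacency-count degree oracle on an undirected simple edge list
degree_oracle <- function(nodes, gene_a, gene_b) {
  deg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_along(gene_a)) {
    deg[gene_a[i]] <- deg[gene_a[i]] + 1L
    deg[gene_b[i]] <- deg[gene_b[i]] + 1L
  }
  deg
}

# group-and-count aggregation oracle for multi-source predictions
aggregate_oracle <- function(predictions, min_sources) {
  key <- paste(predictions$mirna_id, predictions$gene_id, sep = "\r")
  counts <- vapply(split(predictions$source_db, key),
                   function(s) length(unique(s)), 1L)
  keep <- counts >= min_sources
  parts <- strsplit(names(counts)[keep], "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    n_sources = unname(counts[keep]), stringsAsFactors = FALSE)
  out[order(out$mirna_id, out$gene_id), ]
}
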