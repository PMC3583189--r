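# graph builders used across the suite; all return ppi_network objects

path_net <- function(n, prefix = "N") {
  g <- sprintf("%s%02d", prefix, seq_len(n))
  ppi_network(tibble::tibble(gene_a = g[-n], gene_b = g[-1]))
}

clique_edges <- function(genes) {
  p <- utils::combn(genes, 2L)
  tibble::tibble(gene_a = p[1L, ], gene_b = p[2L, ])
}

# two k-cliques joined by a single bridge edge (connected, two planted blocks)
bridged_cliques_net <- function(k = 4) {
  a <- sprintf("A%d", seq_len(k))
  b <- sprintf("B%d", seq_len(k))
  ppi_network(dplyr::bind_rows(clique_edges(a), clique_edges(b),
                               tibble::tibble(gene_a = a[1L], gene_b = b[1L])))
}

star_net <- function(n_leaves, hub = "HUB") {
  ppi_network(tibble::tibble(gene_a = hub,
                             gene_b = sprintf("L%02d", seq_len(n_leaves))))
}

cycle_net <- function(genes) {
  ppi_network(tibble::tibble(gene_a = genes,
                             gene_b = c(genes[-1L], genes[1L])))
}

# Erdos-Renyi G(n, p) conditioned on connectivity, deterministic given seed
random_connected_net <- function(n, p = 0.5, seed = 1) {
  genes <- sprintf("R%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  withr::with_seed(seed, {
    repeat {
      keep <- stats::runif(ncol(pairs)) < p
      if (!any(keep)) next
      e <- tibble::tibble(gene_a = genes[pairs[1L, keep]],
                          gene_b = genes[pairs[2L, keep]])
      g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                         vertices = data.frame(name = genes))
      if (igraph::is_connected(g)) break
    }
    ppi_network(e, genes = genes)
  })
}

# small labeled expression set over given genes: values filled column-major
toy_expression <- function(genes, values, n0 = NULL, labels = NULL) {
  m <- matrix(values, nrow = length(genes))
  rownames(m) <- genes
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  if (is.null(labels)) {
    n0 <- n0 %||% ceiling(ncol(m) / 2)
    labels <- stats::setNames(rep(c(0L, 1L), c(n0, ncol(m) - n0)), colnames(m))
  }
  expression_set(m, labels)
}

# median linear-arrangement cost of n_perm random orderings
random_cost_median <- function(net, n_perm = 100, seed_base = 1000) {
  stats::median(vapply(seq_len(n_perm), function(k) {
    linear_arrangement_cost(net, random_order(net, seed_base + k))
  }, numeric(1)))
}

# block labels (first character) contiguous in an ordering?
blocks_contiguous <- function(ord, block_of) {
  blocks <- block_of(ord$gene[order(ord$position)])
  all(table(rle(blocks)$values) == 1)
}
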