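#' Construct a protein-interaction network
#'
#' An undirected gene graph with per-edge confidence. Edges are stored as a
#' canonical tibble (`gene_a < gene_b`, no self-loops, no duplicates); the
#' gene universe may include isolated genes when given explicitly.
#'
#' @param edges Tibble with columns `gene_a`, `gene_b` and optionally
#'   `confidence` (default 1).
#' @param genes Optional character vector of genes; defaults to the edge
#'   endpoints. Must contain every endpoint.
#' @return An object of class `ppi_network` with fields `genes` (sorted) and
#'   `edges`.
#' @examples
#' net <- ppi_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' net
#' @export
ppi_network <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% names(edges)))
  ga <- toupper(trimws(edges$gene_a))
  gb <- toupper(trimws(edges$gene_b))
  conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence)
          else rep(1, nrow(edges))
  if (any(ga == gb)) rlang::abort("self-interactions are not allowed")
  if (any(conf < 0 | conf > 1)) rlang::abort("edge confidence must lie in [0, 1]")
  e <- tibble::tibble(gene_a = pmin(ga, gb), gene_b = pmax(ga, gb),
                      confidence = conf) |>
    dplyr::summarise(confidence = max(.data$confidence),
                     .by = c("gene_a", "gene_b")) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  universe <- sort(unique(c(e$gene_a, e$gene_b, toupper(trimws(genes)))))
  if (!is.null(genes)) {
    missing <- setdiff(c(e$gene_a, e$gene_b), toupper(trimws(genes)))
    if (length(missing) > 0L) {
      rlang::abort(sprintf("edge endpoints not in gene list: %s",
                           paste(unique(missing), collapse = ", ")))
    }
  }
  structure(list(genes = universe, edges = e), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Number of genes in a network
#' @param net A [ppi_network].
#' @return Integer gene count.
#' @export
n_genes <- function(net) length(net$genes)

#' Convert a network to an igraph object
#'
#' @param net A [ppi_network].
#' @return An undirected `igraph` graph whose vertex names are the genes and
#'   whose `confidence` edge attribute carries the edge scores.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$gene_a, to = net$edges$gene_b,
                   confidence = net$edges$confidence),
    directed = FALSE,
    vertices = data.frame(name = net$genes))
}

#' Symmetric adjacency matrix of a network
#'
#' @param net A [ppi_network].
#' @param weighted If `TRUE`, cells hold edge confidences; otherwise 0/1.
#' @return Symmetric numeric matrix with gene dimnames (genes sorted).
#' @export
adjacency_matrix <- function(net, weighted = FALSE) {
  n <- length(net$genes)
  A <- matrix(0, n, n, dimnames = list(net$genes, net$genes))
  ia <- match(net$edges$gene_a, net$genes)
  ib <- match(net$edges$gene_b, net$genes)
  v <- if (weighted) net$edges$confidence else 1
  A[cbind(ia, ib)] <- v
  A[cbind(ib, ia)] <- v
  A
}

#' Grow a disease-specific subnetwork from seed genes
#'
#' Nearest-neighbour expansion: starting from the seed genes found among the
#' edge-list endpoints, all genes within `hops` interaction steps of any seed
#' are collected, and the subgraph induced on that node set (every input edge
#' with both endpoints inside) is returned.
#'
#' @param edges Edge tibble as returned by [read_edge_list()].
#' @param seeds Character vector of seed genes, or a tibble with a `gene`
#'   column as returned by [read_seed_genes()].
#' @param hops Non-negative expansion depth; `hops = 1` is the classical
#'   nearest-neighbour expansion and the default.
#' @return A [ppi_network]. Seeds absent from the edge list are reported via
#'   a message and attached as attribute `missing_seeds`; found seeds as
#'   attribute `seed_genes`.
#' @export
expand_from_seeds <- function(edges, seeds, hops = 1) {
  stopifnot(length(hops) == 1L, hops >= 0, hops == round(hops))
  if (is.data.frame(seeds)) seeds <- seeds$gene
  seeds <- unique(toupper(trimws(seeds)))
  full <- ppi_network(edges)
  found <- intersect(seeds, full$genes)
  missing <- setdiff(seeds, full$genes)
  if (length(found) == 0L) {
    rlang::abort("seeds not found: no seed gene appears in the edge list")
  }
  if (length(missing) > 0L) {
    message(sprintf("%d seed gene(s) not present in the edge list: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  g <- as_igraph(full)
  reach <- igraph::ego(g, order = hops, nodes = found)
  nodes <- sort(unique(c(found, unlist(lapply(reach, names)))))
  keep <- full$edges$gene_a %in% nodes & full$edges$gene_b %in% nodes
  sub <- full$edges[keep, , drop = FALSE]
  net <- if (nrow(sub) == 0L) {
    structure(list(genes = nodes,
                   edges = tibble::tibble(gene_a = character(),
                                          gene_b = character(),
                                          confidence = numeric())),
              class = "ppi_network")
  } else {
    ppi_network(sub, genes = nodes)
  }
  attr(net, "seed_genes") <- found
  attr(net, "missing_seeds") <- missing
  net
}

#' Extract the largest connected component
#'
#' Reordering by pheromone-biased walks requires a connected graph; this
#' returns the induced subgraph on the largest component, breaking size ties
#' in favour of the component containing the lexicographically smallest gene.
#'
#' @param net A [ppi_network].
#' @return A [ppi_network] restricted to the winning component. Seed
#'   attributes, if present, are restricted accordingly.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "ppi_network"), length(net$genes) >= 1L)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # genes are sorted, so the first gene in a tied component decides
    first_gene <- vapply(best, function(k) {
      min(names(comp$membership)[comp$membership == k])
    }, "")
    best <- best[order(first_gene)][1L]
  }
  nodes <- sort(names(comp$membership)[comp$membership == best])
  keep <- net$edges$gene_a %in% nodes & net$edges$gene_b %in% nodes
  out <- if (any(keep)) ppi_network(net$edges[keep, ], genes = nodes) else
    structure(list(genes = nodes,
                   edges = tibble::tibble(gene_a = character(),
                                          gene_b = character(),
                                          confidence = numeric())),
              class = "ppi_network")
  if (!is.null(attr(net, "seed_genes"))) {
    attr(out, "seed_genes") <- intersect(attr(net, "seed_genes"), nodes)
  }
  out
}

#' Degree vector of a network
#' @param net A [ppi_network].
#' @return Named integer vector of unweighted degrees over all genes.
#' @export
node_degrees <- function(net) {
  deg <- stats::setNames(integer(length(net$genes)), net$genes)
  tab <- table(c(net$edges$gene_a, net$edges$gene_b))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Compute per-gene weights from network topology
#'
#' Degree mode assigns each gene its unweighted degree divided by the maximum
#' degree, so weights lie in (0, 1] with hubs at 1; uniform mode assigns 1 to
#' every gene. Edge confidences never enter the weights.
#'
#' @param net A [ppi_network] (connected component; isolated genes are an
#'   error in degree mode).
#' @param mode `"degree"` or `"uniform"`.
#' @return Tibble with columns `gene`, `weight`; attribute `mode`.
#' @export
compute_gene_weights <- function(net, mode = c("degree", "uniform")) {
  mode <- match.arg(mode)
  deg <- node_degrees(net)
  if (mode == "degree") {
    if (any(deg == 0L)) {
      rlang::abort(sprintf(
        "isolated gene(s) have no degree weight: %s (run largest_connected_component first)",
        paste(names(deg)[deg == 0L], collapse = ", ")))
    }
    w <- deg / max(deg)
  } else {
    w <- stats::setNames(rep(1, length(deg)), names(deg))
  }
  out <- tibble::tibble(gene = names(w), weight = unname(w))
  attr(out, "mode") <- mode
  out
}
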