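new_node_ordering <- function(genes_in_position_order, method) {
  out <- tibble::tibble(gene = genes_in_position_order,
                        position = seq_along(genes_in_position_order))
  attr(out, "method") <- method
  class(out) <- c("node_ordering", class(out))
  out
}

validate_ordering_tbl <- function(ord) {
  n <- nrow(ord)
  if (anyDuplicated(ord$gene) || !setequal(ord$position, seq_len(n))) {
    rlang::abort("ordering must be a bijection from genes onto positions 1..N")
  }
  invisible(ord)
}

#' Ordering method tag
#' @param ord A node ordering.
#' @return The method string (`"acor"`, `"rank"`, `"hclust"`, `"random"`, ...).
#' @export
ordering_method <- function(ord) attr(ord, "method")

check_ordering_matches <- function(net, ord) {
  if (!setequal(ord$gene, net$genes) || nrow(ord) != length(net$genes)) {
    rlang::abort("ordering genes do not match the network's genes")
  }
  invisible(TRUE)
}

#' Linear arrangement cost of an ordering
#'
#' The sum over edges of the absolute positional distance between their
#' endpoints. Orderings that keep interacting genes contiguous score low;
#' minimising this quantity over permutations is the minimum linear
#' arrangement problem.
#'
#' @param net A [ppi_network].
#' @param ord A node ordering covering exactly the network's genes.
#' @return Non-negative number.
#' @export
linear_arrangement_cost <- function(net, ord) {
  check_ordering_matches(net, ord)
  pos <- stats::setNames(ord$position, ord$gene)
  sum(abs(pos[net$edges$gene_a] - pos[net$edges$gene_b]))
}

#' Parameters for ant-colony-optimization reordering
#'
#' @param n_ants Ants per iteration; defaults to the node count (one per
#'   launch node in populated mode).
#' @param walk_length Steps each ant walks per launch.
#' @param alpha Pheromone exponent in the transition rule.
#' @param beta Heuristic exponent; the heuristic term is the destination
#'   node's degree (hub attraction).
#' @param rho Pheromone evaporation rate in (0, 1).
#' @param n_iterations Colony iterations.
#' @param mode `"populated"` launches one ant from every node each iteration;
#'   `"single"` launches `n_ants` ants from one highest-degree node.
#' @param refine_passes Local-search passes (adjacent transpositions plus
#'   single-node relocations) applied to the density ordering.
#' @param pheromone_floor Lower bound keeping every edge reachable.
#' @param seed Integer seed; the whole reordering is deterministic given it.
#' @return A list of class `acor_params`.
#' @export
acor_params <- function(n_ants = NULL, walk_length = 10, alpha = 1, beta = 1,
                        rho = 0.1, n_iterations = 50,
                        mode = c("populated", "single"),
                        refine_passes = 5, pheromone_floor = 1e-6, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(walk_length >= 1, alpha >= 0, beta >= 0,
            rho > 0, rho < 1, n_iterations >= 1,
            refine_passes >= 0, pheromone_floor > 0)
  structure(list(n_ants = n_ants, walk_length = as.integer(walk_length),
                 alpha = alpha, beta = beta, rho = rho,
                 n_iterations = as.integer(n_iterations), mode = mode,
                 refine_passes = as.integer(refine_passes),
                 pheromone_floor = pheromone_floor, seed = as.integer(seed)),
            class = "acor_params")
}

# one full left-to-right sweep of adjacent transpositions; accepts a swap of
# positions (i, i+1) only when it strictly lowers the arrangement cost.
# adj: list, adj[[v]] = integer neighbour ids. Returns updated perm (perm[p] =
# node at position p) and the total cost decrease achieved.
sweep_adjacent_swaps <- function(perm, pos, adj) {
  n <- length(perm)
  gain <- 0
  for (i in seq_len(n - 1L)) {
    u <- perm[i]; v <- perm[i + 1L]
    # delta for u's edges (w != v): |i+1 - pos[w]| - |i - pos[w]|; mirrored for v
    nu <- adj[[u]]; nv <- adj[[v]]
    du <- sum(abs(i + 1L - pos[nu[nu != v]])) - sum(abs(i - pos[nu[nu != v]]))
    dv <- sum(abs(i - pos[nv[nv != u]])) - sum(abs(i + 1L - pos[nv[nv != u]]))
    delta <- du + dv
    if (delta < 0) {
      perm[i] <- v; perm[i + 1L] <- u
      pos[u] <- i + 1L; pos[v] <- i
      gain <- gain + delta
    }
  }
  list(perm = perm, pos = pos, gain = gain)
}

# one sweep of single-node relocations: each node in turn is moved to the
# position minimising the total arrangement cost (a relocation is a run of
# adjacent transpositions; it is accepted only on strict improvement).
sweep_relocations <- function(perm, pos, ia, ib) {
  n <- length(perm)
  cost <- sum(abs(pos[ia] - pos[ib]))
  gain <- 0
  for (u in seq_len(n)) {
    p <- pos[u]
    best_cost <- cost
    best_pos <- NULL
    for (q in seq_len(n)) {
      if (q == p) next
      newpos <- pos
      if (q > p) {
        sel <- pos > p & pos <= q
        newpos[sel] <- pos[sel] - 1L
      } else {
        sel <- pos >= q & pos < p
        newpos[sel] <- pos[sel] + 1L
      }
      newpos[u] <- q
      nc <- sum(abs(newpos[ia] - newpos[ib]))
      if (nc < best_cost) {
        best_cost <- nc
        best_pos <- newpos
      }
    }
    if (!is.null(best_pos)) {
      gain <- gain + (best_cost - cost)
      cost <- best_cost
      pos <- best_pos
    }
  }
  perm <- integer(n)
  perm[pos] <- seq_len(n)
  list(perm = perm, pos = pos, gain = gain)
}

#' Reorder network nodes with the ant-colony-optimization heuristic
#'
#' Simulated ants walk the network with transition probabilities proportional
#' to `pheromone^alpha * degree^beta`, depositing pheromone on traversed
#' edges (evaporated at rate `rho` per iteration, floored at
#' `pheromone_floor`). Visit counts accumulate into a node density
#' distribution, normalized to sum to one after every iteration. Nodes are
#' first ranked by final density (descending, ties broken by gene symbol),
#' then `refine_passes` local-search sweeps refine that order: each pass
#' runs one sweep of adjacent transpositions followed by one sweep of
#' single-node relocations (each relocation being a run of adjacent
#' transpositions), accepting only moves that strictly decrease
#' [linear_arrangement_cost()]. The returned ordering's cost therefore never
#' exceeds the density ordering's cost.
#'
#' @param net A connected [ppi_network] with at least two genes.
#' @param params An [acor_params] list.
#' @return A `node_ordering` tibble (class `acor_ordering`) with attributes
#'   `cost`, `initial_cost` (density ordering, pre-refinement), `density`
#'   (named, sums to 1) and `params`.
#' @export
acor_reorder <- function(net, params = acor_params()) {
  stopifnot(inherits(net, "ppi_network"), inherits(params, "acor_params"))
  n <- length(net$genes)
  if (n < 2L) rlang::abort("reordering needs at least 2 genes")
  if (!igraph::is_connected(as_igraph(net))) {
    rlang::abort("network is disconnected; apply largest_connected_component() first")
  }
  genes <- net$genes
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  m <- length(ia)
  # adjacency as index lists; edge_id[[v]] maps neighbour slot -> edge index
  adj <- vector("list", n)
  eid <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k]); eid[[ia[k]]] <- c(eid[[ia[k]]], k)
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k]); eid[[ib[k]]] <- c(eid[[ib[k]]], k)
  }
  deg <- lengths(adj)
  n_ants <- if (is.null(params$n_ants)) n else as.integer(params$n_ants)

  tau <- rep(1, m)
  visits <- rep(0, n)
  deposit_unit <- 1 / params$walk_length

  withr::with_seed(params$seed, {
    for (iter in seq_len(params$n_iterations)) {
      starts <- if (params$mode == "populated") seq_len(n) else {
        top <- which(deg == max(deg))
        rep(top[order(genes[top])][1L], n_ants)
      }
      deposits <- rep(0, m)
      for (s in starts) {
        cur <- s
        visits[cur] <- visits[cur] + 1
        for (step in seq_len(params$walk_length)) {
          nb <- adj[[cur]]
          if (length(nb) == 1L) {
            pick <- 1L
          } else {
            w <- tau[eid[[cur]]]^params$alpha * deg[nb]^params$beta
            pick <- sample.int(length(nb), 1L, prob = w)
          }
          deposits[eid[[cur]][pick]] <- deposits[eid[[cur]][pick]] + deposit_unit
          cur <- nb[pick]
          visits[cur] <- visits[cur] + 1
        }
      }
      tau <- pmax((1 - params$rho) * tau + deposits, params$pheromone_floor)
    }
  })
  density <- visits / sum(visits)

  # density ordering: descending density, ties by gene symbol
  init <- order(-density, genes)
  pos <- integer(n); pos[init] <- seq_len(n)
  pos_cost <- function(p) sum(abs(p[ia] - p[ib]))
  initial_cost <- pos_cost(pos)

  perm <- init
  if (params$refine_passes > 0L && m > 0L) {
    for (pass in seq_len(params$refine_passes)) {
      res <- sweep_adjacent_swaps(perm, pos, adj)
      perm <- res$perm; pos <- res$pos
      rel <- sweep_relocations(perm, pos, ia, ib)
      perm <- rel$perm; pos <- rel$pos
      if (res$gain + rel$gain == 0) break
    }
  }
  final_cost <- pos_cost(pos)

  out <- new_node_ordering(genes[perm], method = "acor")
  class(out) <- c("acor_ordering", class(out))
  attr(out, "cost") <- final_cost
  attr(out, "initial_cost") <- initial_cost
  attr(out, "density") <- stats::setNames(density, genes)
  attr(out, "params") <- params
  out
}

#' Rank nodes by damped random-walk stationary probability
#'
#' Power iteration of the PageRank-style recursion
#' `p <- (1 - damping)/N + damping * t(P) p` with `P` the row-stochastic
#' transition matrix of the unweighted graph, iterated until the L1 change
#' drops below `tol`. The ordering is by descending score with lexicographic
#' tie-breaking.
#'
#' @param net A connected [ppi_network].
#' @param damping Damping factor in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A `node_ordering` with attribute `score` (named, sums to 1).
#' @export
random_walk_rank <- function(net, damping = 0.85, tol = 1e-10,
                             max_iter = 10000L) {
  stopifnot(damping > 0, damping < 1, tol > 0)
  if (!igraph::is_connected(as_igraph(net))) {
    rlang::abort("network is disconnected; apply largest_connected_component() first")
  }
  genes <- net$genes
  n <- length(genes)
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  deg <- as.numeric(node_degrees(net))
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- p / deg
    nxt <- rep((1 - damping) / n, n)
    # undirected: mass flows both ways along each edge
    flow_a <- damping * contrib[ia]
    flow_b <- damping * contrib[ib]
    agg <- tapply(c(flow_a, flow_b), c(ib, ia), sum)
    nxt[as.integer(names(agg))] <- nxt[as.integer(names(agg))] + as.numeric(agg)
    if (sum(abs(nxt - p)) < tol) {
      p <- nxt
      ord <- order(-p, genes)
      out <- new_node_ordering(genes[ord], method = "rank")
      attr(out, "score") <- stats::setNames(p, genes)
      return(out)
    }
    p <- nxt
  }
  rlang::abort(sprintf("random-walk ranking did not converge in %d iterations",
                       max_iter))
}

# deterministic leaf order for an hclust merge tree: at every internal node
# the smaller cluster comes first; ties broken by the lexicographically
# smallest member gene.
hclust_leaf_order <- function(merge, labels) {
  resolve <- function(k) {
    if (k < 0) return(list(leaves = -k, min_lab = labels[-k], size = 1L))
    a <- resolve(merge[k, 1L])
    b <- resolve(merge[k, 2L])
    swap <- (b$size < a$size) ||
      (b$size == a$size && b$min_lab < a$min_lab)
    if (swap) { tmp <- a; a <- b; b <- tmp }
    list(leaves = c(a$leaves, b$leaves),
         min_lab = min(a$min_lab, b$min_lab),
         size = a$size + b$size)
  }
  resolve(nrow(merge))$leaves
}

#' Order nodes by hierarchical clustering of neighbourhood similarity
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `d(u, v) = 1 - Jaccard(N[u], N[v])` of closed neighbourhoods, the standard
#' graph analogue of 2-D hierarchical clustering of an adjacency matrix. The
#' ordering is the dendrogram leaf order with deterministic child ordering
#' (smaller cluster first, ties by smallest member gene).
#'
#' @param net A [ppi_network] with at least two genes.
#' @return A `node_ordering` with attribute `hclust` (the tree).
#' @export
hclust_order <- function(net) {
  genes <- net$genes
  n <- length(genes)
  if (n < 2L) rlang::abort("clustering needs at least 2 genes")
  A <- adjacency_matrix(net)
  diag(A) <- 1  # closed neighbourhoods
  inter <- A %*% t(A)          # |N[u] & N[v]| for 0/1 rows
  sz <- diag(inter)
  uni <- outer(sz, sz, "+") - inter
  D <- 1 - inter / uni
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  leaves <- hclust_leaf_order(hc$merge, genes)
  out <- new_node_ordering(genes[leaves], method = "hclust")
  attr(out, "hclust") <- hc
  out
}

#' Uniform random node ordering
#'
#' @param net A [ppi_network].
#' @param seed Integer seed; the permutation is uniform and deterministic
#'   given it.
#' @return A `node_ordering`.
#' @export
random_order <- function(net, seed) {
  genes <- net$genes
  perm <- withr::with_seed(as.integer(seed), sample(length(genes)))
  new_node_ordering(genes[perm], method = "random")
}

# all permutations of 1..n in lexicographic order, as an (n! x n) matrix
perms_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  vals <- seq_len(n)
  for (first in vals) {
    rest <- vals[-first]
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(first, block)
    row <- row + nrow(sub)
  }
  out
}

#' Exact minimum linear arrangement by exhaustive search
#'
#' Brute-force oracle for tiny graphs: evaluates
#' [linear_arrangement_cost()] over all `N!` orderings and returns the
#' first-lexicographic minimizer (orderings read as gene sequences in
#' position order).
#'
#' @param net A [ppi_network] with at most 9 genes.
#' @return List with `ordering` (a `node_ordering`, method `"exact"`) and
#'   `cost`.
#' @export
brute_force_min_arrangement <- function(net) {
  n <- length(net$genes)
  if (n > 9L) {
    rlang::abort("exhaustive search is limited to networks with at most 9 genes")
  }
  genes <- net$genes  # sorted, so row-wise lexicographic order of sequences
  P <- perms_lex(n)
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  cost <- rep(0, nrow(P))
  # P[k, j] = gene index at position j; need positions of each gene
  pos <- matrix(0L, nrow(P), n)
  pos[cbind(rep(seq_len(nrow(P)), n), as.vector(P))] <-
    rep(seq_len(n), each = nrow(P))
  for (k in seq_along(ia)) {
    cost <- cost + abs(pos[, ia[k]] - pos[, ib[k]])
  }
  best <- which.min(cost)  # first index = first-lexicographic gene sequence
  ord <- new_node_ordering(genes[P[best, ]], method = "exact")
  list(ordering = ord, cost = cost[best])
}

#' Compute a node ordering by a named method
#'
#' Dispatch helper used by the sweep harness and the command-line interface.
#'
#' @param net A connected [ppi_network].
#' @param method One of `"acor"`, `"rank"`, `"hclust"`, `"random"`.
#' @param seed Seed for the stochastic methods.
#' @param acor An [acor_params] list for `method = "acor"` (its `seed` field
#'   is replaced by `seed`).
#' @param damping,tol Passed to [random_walk_rank()].
#' @return A `node_ordering`.
#' @export
compute_ordering <- function(net, method = c("acor", "rank", "hclust", "random"),
                             seed = 1L, acor = acor_params(),
                             damping = 0.85, tol = 1e-10) {
  method <- match.arg(method)
  switch(method,
         acor = { acor$seed <- as.integer(seed); acor_reorder(net, acor) },
         rank = random_walk_rank(net, damping = damping, tol = tol),
         hclust = hclust_order(net),
         random = random_order(net, seed))
}

#' @method tidy acor_ordering
#' @export
tidy.acor_ordering <- function(x, ...) {
  tibble::tibble(gene = x$gene, position = x$position,
                 density = unname(attr(x, "density")[x$gene]))
}

#' One-row summary of an ant-colony reordering
#'
#' @param x An `acor_ordering`.
#' @param ... Unused.
#' @return Tibble with the gene count, final and pre-refinement arrangement
#'   costs, and the relative cost reduction achieved by local search.
#' @method glance acor_ordering
#' @export
glance.acor_ordering <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 cost = attr(x, "cost"),
                 initial_cost = attr(x, "initial_cost"),
                 refinement_gain = attr(x, "initial_cost") - attr(x, "cost"))
}
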