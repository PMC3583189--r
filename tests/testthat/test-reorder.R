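ordering_from <- function(genes_in_order) new_ordering_for_test(genes_in_order)

new_ordering_for_test <- function(genes_in_order) {
  out <- tibble::tibble(gene = genes_in_order,
                        position = seq_along(genes_in_order))
  attr(out, "method") <- "manual"
  out
}

test_that("linear arrangement cost sums positional edge lengths", {
  p3 <- path_net(3)
  expect_equal(linear_arrangement_cost(p3, ordering_from(p3$genes)), 2)

  tri <- ppi_network(clique_edges(c("A", "B", "C")))
  for (perm in list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B"))) {
    expect_equal(linear_arrangement_cost(tri, ordering_from(perm)), 4)
  }

  star <- star_net(3)
  ord <- ordering_from(c("L01", "HUB", "L02", "L03"))
  expect_equal(linear_arrangement_cost(star, ord), 4)
  expect_equal(brute_force_min_arrangement(star)$cost, 4)

  expect_error(linear_arrangement_cost(p3, ordering_from(c("X", "Y", "Z"))),
               "match")
})

test_that("brute-force minimum arrangement is exact on tiny graphs", {
  expect_equal(brute_force_min_arrangement(path_net(4))$cost, 3)

  k4 <- ppi_network(clique_edges(c("A", "B", "C", "D")))
  bf <- brute_force_min_arrangement(k4)
  expect_equal(bf$cost, 10)
  # complete-graph cost is permutation invariant
  expect_equal(linear_arrangement_cost(k4, random_order(k4, 5)), 10)

  single <- ppi_network(tibble::tibble(gene_a = "A", gene_b = "B"))
  expect_equal(brute_force_min_arrangement(single)$cost, 1)

  expect_error(brute_force_min_arrangement(path_net(10)), "at most 9")
})

test_that("ant-colony reordering finds the optimal path arrangement with default settings", {
  p5 <- path_net(5)
  for (s in c(1, 7, 23)) {
    ord <- acor_reorder(p5, acor_params(seed = s))
    expect_equal(attr(ord, "cost"), 4)
  }
})

test_that("ant-colony reordering is a deterministic bijection with monotone refinement", {
  net <- random_connected_net(12, p = 0.3, seed = 4)
  o1 <- acor_reorder(net, acor_params(seed = 11))
  o2 <- acor_reorder(net, acor_params(seed = 11))
  expect_equal(o1$gene, o2$gene)
  expect_equal(o1$position, o2$position)
  expect_setequal(o1$gene, net$genes)
  expect_setequal(o1$position, seq_along(net$genes))
  expect_lte(attr(o1, "cost"), attr(o1, "initial_cost"))
  expect_equal(sum(attr(o1, "density")), 1)

  o3 <- acor_reorder(net, acor_params(seed = 12))
  expect_equal(attr(o3, "cost"),
               linear_arrangement_cost(net, o3))

  g <- glance(o1)
  expect_equal(g$cost + g$refinement_gain, g$initial_cost)
  expect_equal(nrow(tidy(o1)), 12L)
})

test_that("ant-colony reordering rejects degenerate input", {
  disconnected <- ppi_network(tibble::tibble(gene_a = c("A", "C"),
                                             gene_b = c("B", "D")))
  expect_error(acor_reorder(disconnected), "largest_connected_component")
  one <- structure(list(genes = "A",
                        edges = tibble::tibble(gene_a = character(),
                                               gene_b = character(),
                                               confidence = numeric())),
                   class = "ppi_network")
  expect_error(acor_reorder(one), "at least 2")
})

test_that("two bridged cliques end up block-contiguous for every seed", {
  net <- bridged_cliques_net(4)
  for (s in 1:20) {
    ord <- acor_reorder(net, acor_params(seed = s))
    expect_true(blocks_contiguous(ord, function(g) substr(g, 1, 1)),
                label = sprintf("contiguous blocks at seed %d", s))
  }
})

test_that("single launch mode also yields valid orderings", {
  net <- bridged_cliques_net(3)
  ord <- acor_reorder(net, acor_params(mode = "single", n_ants = 5, seed = 3))
  expect_setequal(ord$position, seq_along(net$genes))
  expect_lte(attr(ord, "cost"), attr(ord, "initial_cost"))
})

test_that("random-walk ranking matches power-iteration expectations and tie rules", {
  star <- star_net(4)
  ord <- random_walk_rank(star)
  expect_equal(ord$gene[ord$position == 1], "HUB")

  # independent oracle: igraph's PageRank on the same graph
  pr <- igraph::page_rank(as_igraph(star), damping = 0.85)$vector
  expect_equal(unname(attr(ord, "score")[names(pr)]), unname(pr),
               tolerance = 1e-6)

  c4 <- cycle_net(c("A", "B", "C", "D"))
  expect_equal(random_walk_rank(c4)$gene, c("A", "B", "C", "D"))

  ab <- ppi_network(tibble::tibble(gene_a = "B", gene_b = "A"))
  expect_equal(random_walk_rank(ab)$gene, c("A", "B"))

  expect_error(random_walk_rank(star, tol = 0), "tol")
})

test_that("neighbourhood-Jaccard clustering orders structural blocks together", {
  net <- bridged_cliques_net(4)
  ord <- hclust_order(net)
  expect_setequal(ord$position, 1:8)
  expect_true(blocks_contiguous(ord, function(g) substr(g, 1, 1)))

  two <- ppi_network(tibble::tibble(gene_a = "B", gene_b = "A"))
  expect_equal(hclust_order(two)$gene, c("A", "B"))

  # triangle vertices are twins: identical closed neighbourhoods, d = 0
  A <- adjacency_matrix(ppi_network(clique_edges(c("A", "B", "C"))))
  diag(A) <- 1
  jac <- function(u, v) sum(A[u, ] & A[v, ]) / sum(A[u, ] | A[v, ])
  expect_equal(1 - jac("A", "B"), 0)
})

test_that("random orderings are deterministic, valid, and uniform", {
  net <- path_net(3)
  expect_equal(random_order(net, 42), random_order(net, 42))
  expect_setequal(random_order(net, 1)$position, 1:3)

  one <- ppi_network(tibble::tibble(gene_a = "A", gene_b = "B"))
  expect_setequal(random_order(one, 5)$position, 1:2)

  # all 6 permutations of 3 genes appear with frequency 1/6 +- 0.05
  perms <- vapply(1:1000, function(s) {
    paste(random_order(net, s)$gene, collapse = "")
  }, "")
  freq <- table(perms) / 1000
  expect_equal(length(freq), 6L)
  expect_true(all(abs(freq - 1 / 6) < 0.05))
})

test_that("heuristic cost sits between the optimum and random medians on small graphs", {
  for (s in 1:5) {
    n <- 5 + (s %% 4)
    net <- random_connected_net(n, p = 0.45, seed = 100 + s)
    opt <- brute_force_min_arrangement(net)$cost
    acor <- attr(acor_reorder(net, acor_params(seed = s)), "cost")
    med <- random_cost_median(net, n_perm = 50, seed_base = s * 500)
    expect_lte(opt, acor)
    expect_lte(acor, med)
  }
})

test_that("compute_ordering dispatches and tags methods", {
  net <- bridged_cliques_net(3)
  for (m in c("acor", "rank", "hclust", "random")) {
    ord <- compute_ordering(net, m, seed = 2)
    expect_equal(ordering_method(ord), if (m == "acor") "acor" else m)
    expect_setequal(ord$position, seq_along(net$genes))
  }
})
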