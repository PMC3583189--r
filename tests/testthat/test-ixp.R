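# direct summation oracle for the integrated profile, independent of the
# matrix-based implementation path
integrate_oracle <- function(x_by_pos, w_by_pos, sigma) {
  n <- length(x_by_pos)
  vapply(seq_len(n), function(i) {
    sum(w_by_pos * x_by_pos * gaussian_influence(i - seq_len(n), sigma))
  }, numeric(1))
}

manual_ordering <- function(genes) {
  out <- tibble::tibble(gene = genes, position = seq_along(genes))
  attr(out, "method") <- "manual"
  out
}

uniform_weights <- function(genes) {
  out <- tibble::tibble(gene = genes, weight = 1)
  attr(out, "mode") <- "uniform"
  out
}

test_that("gaussian influence matches its closed form and delta-kernel limit", {
  expect_equal(gaussian_influence(0, 3), 1)
  expect_equal(gaussian_influence(0, 0.001), 1)
  expect_equal(gaussian_influence(2, 2), exp(-0.5))
  expect_equal(gaussian_influence(5, 0), 0)
  expect_equal(gaussian_influence(0, 0), 1)
  expect_equal(gaussian_influence(-3, 2), gaussian_influence(3, 2))
  expect_equal(kernel_l2_norm(0, 40), 1)
  expect_gt(kernel_l2_norm(0.5, 40), kernel_l2_norm(0.1, 40))
})

test_that("profile integration reduces to the weighted profile at r = 0 and spreads Gaussianly", {
  genes <- c("G1", "G2", "G3")
  ord <- manual_ordering(genes)
  w <- uniform_weights(genes)
  x <- c(G1 = 1, G2 = 0, G3 = 0)

  expect_equal(as.numeric(integrate_profile(x, ord, w, ixp_params(r = 0))),
               c(1, 0, 0))

  # sigma = 1 via r * base_bandwidth = 0.1 * 10
  prof <- integrate_profile(x, ord, w, ixp_params(r = 0.1, base_bandwidth = 10))
  expect_equal(as.numeric(prof), c(1, exp(-1 / 2), exp(-2)))
})

test_that("closely ordered weak genes superpose into a peak exceeding a lone strong gene's spread", {
  genes <- sprintf("G%d", 1:5)
  ord <- manual_ordering(genes)
  w <- uniform_weights(genes)
  sigma <- 1
  params <- ixp_params(r = 0.1, base_bandwidth = 10)

  weak_trio <- c(G1 = 0, G2 = 0.4, G3 = 0.4, G4 = 0.4, G5 = 0)
  singleton <- c(G1 = 1, G2 = 0, G3 = 0, G4 = 0, G5 = 0)

  f_weak <- as.numeric(integrate_profile(weak_trio, ord, w, params))
  f_single <- as.numeric(integrate_profile(singleton, ord, w, params))

  # oracle agreement
  expect_equal(f_weak, integrate_oracle(weak_trio, rep(1, 5), sigma))
  expect_equal(f_single, integrate_oracle(singleton, rep(1, 5), sigma))

  # the trio's centre peak: 0.4 * (1 + 2 exp(-1/2)) = 0.885...
  expect_equal(f_weak[3], 0.4 * (1 + 2 * exp(-0.5)), tolerance = 1e-12)
  # it dominates everything the lone gene radiates beyond its own position,
  # and doubly so beyond the adjacent one
  expect_gt(f_weak[3], max(f_single[-1]))
  expect_gt(f_weak[3], 2 * max(f_single[-(1:2)]))
})

test_that("profile integration is linear and handles missing genes as configured", {
  genes <- sprintf("G%d", 1:6)
  ord <- manual_ordering(genes)
  w <- uniform_weights(genes)
  params <- ixp_params(r = 0.25)
  withr::with_seed(8, {
    x <- stats::setNames(stats::rnorm(6), genes)
    y <- stats::setNames(stats::rnorm(6), genes)
  })
  lhs <- integrate_profile(2 * x - 3 * y, ord, w, params)
  rhs <- 2 * integrate_profile(x, ord, w, params) -
    3 * integrate_profile(y, ord, w, params)
  expect_equal(as.numeric(lhs), as.numeric(rhs))

  # genes absent from the ordering are counted; absent expression contributes
  # the configured placeholder
  x2 <- c(G1 = 1, NOTINNET = 5)
  prof <- integrate_profile(x2, ord, w, ixp_params(r = 0))
  expect_equal(attr(prof, "n_unmapped"), 1L)
  expect_equal(as.numeric(prof), c(1, 0, 0, 0, 0, 0))
  prof2 <- integrate_profile(x2, ord, w,
                             ixp_params(r = 0, missing_expression_value = -1))
  expect_equal(as.numeric(prof2), c(1, -1, -1, -1, -1, -1))
})

test_that("dataset transform at r = 0 is exactly the permuted weighted matrix", {
  net <- random_connected_net(8, p = 0.5, seed = 3)
  em <- toy_expression(net$genes, stats::rnorm(8 * 4))
  ord <- random_order(net, 17)
  w <- compute_gene_weights(net, "degree")
  fm <- transform_dataset(em, ord, w, ixp_params(r = 0), "none")
  wv <- stats::setNames(w$weight, w$gene)
  genes_by_pos <- ord$gene[order(ord$position)]
  expected <- t(em$values[genes_by_pos, ] * wv[genes_by_pos])
  expect_equal(unname(fm$values), unname(expected))
  expect_equal(fm$provenance$method, "random")
})

test_that("per-gene standardization zeroes constant genes and keeps identical samples identical", {
  genes <- c("G1", "G2", "G3")
  vals <- matrix(c(1, 5, 2, 1, 5, 4, 1, 5, 6, 1, 5, 8), nrow = 3)
  rownames(vals) <- genes
  colnames(vals) <- sprintf("S%02d", 1:4)
  em <- expression_set(vals, stats::setNames(c(0, 0, 1, 1), colnames(vals)))
  ord <- manual_ordering(genes)
  w <- uniform_weights(genes)
  fm <- transform_dataset(em, ord, w, ixp_params(r = 0.2), "per_gene_z")
  # constant genes G1 and G2 contribute nothing anywhere
  expect_equal(unname(fm$values[, 1]),
               unname(fm$values[, 3]) * gaussian_influence(2, 2))

  em2 <- toy_expression(genes, rep(c(1, 2, 3), 2), n0 = 1)
  fm2 <- transform_dataset(em2, ord, w, ixp_params(r = 0.4), "per_gene_z")
  expect_equal(fm2$values[1, ], fm2$values[2, ])

  expect_error(
    transform_dataset(toy_expression(c("X1", "X2"), 1:4), ord, w, ixp_params()),
    "no genes shared")
})

test_that("per-unit-mass smoothing never increases total variation as r grows", {
  net <- random_connected_net(15, p = 0.3, seed = 6)
  ord <- acor_reorder(net, acor_params(seed = 1))
  w <- compute_gene_weights(net, "degree")
  tv <- function(v) sum(abs(diff(v)))
  for (case in 1:20) {
    x <- withr::with_seed(case, stats::setNames(stats::rnorm(15), net$genes))
    tvs <- vapply(seq(0, 0.9, 0.1), function(r) {
      tv(as.numeric(integrate_profile(x, ord, w, ixp_params(r = r)))) /
        kernel_l1_norm(r, 15)
    }, numeric(1))
    expect_true(all(diff(tvs) <= 1e-9),
                label = sprintf("TV non-increasing, case %d", case))
  }
})

test_that("consistent gene relabeling leaves the feature matrix unchanged", {
  net <- random_connected_net(10, p = 0.4, seed = 9)
  em <- toy_expression(net$genes, stats::rnorm(40))
  ord <- acor_reorder(net, acor_params(seed = 2))
  w <- compute_gene_weights(net, "degree")
  fm <- transform_dataset(em, ord, w, ixp_params(r = 0.3), "per_gene_z")

  # rename every gene; permute expression rows; keep ordering/weights aligned
  map <- stats::setNames(sprintf("Z%02d", seq_along(net$genes)), net$genes)
  perm <- withr::with_seed(1, sample(length(net$genes)))
  vals2 <- em$values[perm, ]
  rownames(vals2) <- unname(map[rownames(vals2)])
  em2 <- expression_set(vals2, em$labels)
  ord2 <- ord
  ord2$gene <- unname(map[ord$gene])
  w2 <- tibble::tibble(gene = unname(map[w$gene]), weight = w$weight)
  attr(w2, "mode") <- "degree"
  fm2 <- transform_dataset(em2, ord2, w2, ixp_params(r = 0.3), "per_gene_z")
  expect_equal(unname(fm2$values), unname(fm$values))
})

test_that("group averages are per-class arithmetic means of feature rows", {
  genes <- c("G1", "G2")
  ord <- manual_ordering(genes)
  w <- uniform_weights(genes)

  em <- toy_expression(genes, c(0, 2, 2, 0), n0 = 1)
  fm <- transform_dataset(em, ord, w, ixp_params(r = 0), "none")
  avg <- group_average_profile(fm)
  expect_equal(avg$value[avg$class == "0"], c(0, 2))
  expect_equal(avg$value[avg$class == "1"], c(2, 0))

  em2 <- toy_expression(genes, c(1, 3, 1, 3, 7, 9), n0 = 2)
  fm2 <- transform_dataset(em2, ord, w, ixp_params(r = 0), "none")
  avg2 <- group_average_profile(fm2)
  expect_equal(avg2$value[avg2$class == "0"], c(1, 3))

  fm2$labels <- stats::setNames(rep(0L, 3), colnames(em2$values))
  expect_error(group_average_profile(fm2), "has no samples")
})
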