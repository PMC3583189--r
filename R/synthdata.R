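#' Configuration for the planted-partition synthetic benchmark
#'
#' The generator emulates the statistical structure the integrative
#' transform assumes: a modular interaction graph, and two-group expression
#' in which a subset of modules carries coordinated weak per-gene shifts —
#' too weak to detect gene-by-gene — while a few isolated genes carry strong
#' shifts. The defaults define the package's reference benchmark scenario:
#' 4 modules of 10 genes (`p_in = 0.9`, `p_out = 0.03`), 20 samples per
#' class, weak shifts of 0.4 noise-sd in half the modules, and 2 strong
#' (2 sd) singleton markers in unaffected modules.
#'
#' @param n_modules Number of planted modules (>= 2).
#' @param module_size Genes per module (>= 3).
#' @param p_in Intra-module edge probability, in (0, 1].
#' @param p_out Inter-module edge probability, in \[0, 1); must be `< p_in`.
#' @param n_samples_per_class Samples per class (>= 3) in each generated
#'   dataset.
#' @param weak_effect Per-gene mean shift in affected modules, in noise-sd
#'   units; must be `< strong_effect`.
#' @param strong_effect Mean shift of the isolated marker genes, in noise-sd
#'   units.
#' @param n_strong_singletons Number of strongly shifted isolated genes,
#'   drawn from unaffected modules.
#' @param noise_sd Within-class standard deviation of expression noise.
#' @param affected_fraction Fraction of modules carrying the weak shift, in
#'   (0, 1].
#' @param seed Master seed; everything downstream is deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_modules = 4, module_size = 10,
                         p_in = 0.9, p_out = 0.03,
                         n_samples_per_class = 20,
                         weak_effect = 0.4, strong_effect = 2,
                         n_strong_singletons = 2, noise_sd = 1,
                         affected_fraction = 0.5, seed = 1L) {
  stopifnot(n_modules >= 2, module_size >= 3,
            p_in > 0, p_in <= 1, p_out >= 0, p_out < 1,
            n_samples_per_class >= 3, noise_sd > 0,
            affected_fraction > 0, affected_fraction <= 1,
            n_strong_singletons >= 0)
  if (p_in <= p_out) rlang::abort("modules must be assortative: p_in > p_out")
  # strict inequality except in the null scenario where both effects vanish
  if (weak_effect > strong_effect ||
      (weak_effect == strong_effect && weak_effect != 0)) {
    rlang::abort("weak_effect must not exceed strong_effect (equal only when both are 0)")
  }
  structure(list(n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 p_in = p_in, p_out = p_out,
                 n_samples_per_class = as.integer(n_samples_per_class),
                 weak_effect = weak_effect, strong_effect = strong_effect,
                 n_strong_singletons = as.integer(n_strong_singletons),
                 noise_sd = noise_sd, affected_fraction = affected_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_gene_names <- function(cfg) {
  as.vector(vapply(seq_len(cfg$n_modules), function(m) {
    sprintf("M%dG%02d", m, seq_len(cfg$module_size))
  }, character(cfg$module_size)))
}

#' Generate a planted-partition interaction network
#'
#' Draws intra-module edges with probability `p_in` and inter-module edges
#' with `p_out`, resampling (up to 100 attempts) until the graph is
#' connected. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config].
#' @return List with `network` (a [ppi_network]) and `modules` (tibble
#'   `gene`, `module` — the planted ground truth).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- synth_gene_names(cfg)
  module <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
  n <- length(genes)
  pairs <- utils::combn(n, 2L)
  same <- module[pairs[1L, ]] == module[pairs[2L, ]]
  p <- ifelse(same, cfg$p_in, cfg$p_out)

  edges <- withr::with_seed(cfg$seed, {
    for (attempt in seq_len(100L)) {
      keep <- stats::runif(ncol(pairs)) < p
      e <- tibble::tibble(gene_a = genes[pairs[1L, keep]],
                          gene_b = genes[pairs[2L, keep]],
                          confidence = 1)
      if (nrow(e) > 0L) {
        g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE,
                                           vertices = data.frame(name = genes))
        if (igraph::is_connected(g)) break
      }
      e <- NULL
    }
    e
  })
  if (is.null(edges)) {
    rlang::abort("could not generate a connected network in 100 attempts; increase p_out")
  }
  list(network = ppi_network(edges, genes = genes),
       modules = tibble::tibble(gene = genes, module = module))
}

affected_modules <- function(cfg) {
  seq_len(ceiling(cfg$affected_fraction * cfg$n_modules))
}

# strong singleton markers are a fixed property of the scenario (like real
# disease genes), so they are chosen from the master seed, not the draw seed
singleton_genes <- function(cfg, modules) {
  pool <- modules$gene[!modules$module %in% affected_modules(cfg)]
  if (cfg$n_strong_singletons > length(pool)) {
    rlang::abort(sprintf(
      "n_strong_singletons = %d exceeds the %d genes in unaffected modules",
      cfg$n_strong_singletons, length(pool)))
  }
  if (cfg$n_strong_singletons == 0L) return(character())
  withr::with_seed(cfg$seed, sort(sample(pool, cfg$n_strong_singletons)))
}

#' Generate two-class expression data over a planted network
#'
#' Class 0 expression is Normal(0, `noise_sd^2`) per gene and sample. In
#' class 1, every gene of the first `ceiling(affected_fraction * n_modules)`
#' modules is shifted by `+weak_effect * noise_sd`, and
#' `n_strong_singletons` marker genes in unaffected modules (fixed by the
#' master seed) are shifted by `+strong_effect * noise_sd`.
#'
#' @param cfg A [synth_config].
#' @param modules Module tibble from [generate_network()].
#' @param seed Seed for the expression draw (defaults to `cfg$seed`); the
#'   identity of the shifted genes depends only on `cfg`, so independent
#'   draws share the same signal genes.
#' @return An [expression_set] (classes `control`/`case`) with attributes
#'   `weak_genes` and `singleton_genes`.
#' @export
generate_expression <- function(cfg, modules, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"), is.data.frame(modules))
  genes <- modules$gene
  n <- length(genes)
  ns <- cfg$n_samples_per_class
  weak <- modules$gene[modules$module %in% affected_modules(cfg)]
  strong <- singleton_genes(cfg, modules)

  shift <- stats::setNames(rep(0, n), genes)
  shift[weak] <- cfg$weak_effect * cfg$noise_sd
  shift[strong] <- cfg$strong_effect * cfg$noise_sd

  vals <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(n * 2L * ns, sd = cfg$noise_sd), n, 2L * ns)
  })
  vals[, (ns + 1L):(2L * ns)] <- vals[, (ns + 1L):(2L * ns)] + shift
  samples <- c(sprintf("CTRL%02d", seq_len(ns)), sprintf("CASE%02d", seq_len(ns)))
  rownames(vals) <- genes
  colnames(vals) <- samples
  labels <- stats::setNames(rep(0:1, each = ns), samples)
  out <- expression_set(vals, labels, classes = c("control", "case"))
  attr(out, "weak_genes") <- weak
  attr(out, "singleton_genes") <- strong
  out
}

#' Generate a complete benchmark case
#'
#' One planted network plus two independent expression draws (train and
#' test) with seeds derived from the master seed; the shifted gene sets are
#' shared between the draws.
#'
#' @param cfg A [synth_config].
#' @return List of class `ixp_case`: `network`, `modules`, `train`, `test`,
#'   `config`.
#' @export
generate_case <- function(cfg) {
  gn <- generate_network(cfg)
  draw_seeds <- withr::with_seed(cfg$seed, sample.int(.Machine$integer.max, 2L))
  list(network = gn$network, modules = gn$modules,
       train = generate_expression(cfg, gn$modules, seed = draw_seeds[1L]),
       test = generate_expression(cfg, gn$modules, seed = draw_seeds[2L]),
       config = cfg) |>
    structure(class = "ixp_case")
}

#' Serialize a benchmark case through the package's tabular formats
#'
#' Writes `edges.tsv`, `seeds.tsv` (one gene per affected module, class I),
#' `train.tsv`/`train_labels.tsv` and `test.tsv`/`test_labels.tsv`, so the
#' file-based pipeline can be exercised end to end.
#'
#' @param case List from [generate_case()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(case$network, file.path(dir, "edges.tsv"))
  aff <- affected_modules(case$config)
  seeds <- vapply(aff, function(m) min(case$modules$gene[case$modules$module == m]), "")
  writeLines(paste(seeds, "I", sep = "\t"), file.path(dir, "seeds.tsv"))
  write_expression(case$train, file.path(dir, "train.tsv"),
                   file.path(dir, "train_labels.tsv"))
  write_expression(case$test, file.path(dir, "test.tsv"),
                   file.path(dir, "test_labels.tsv"))
  invisible(dir)
}
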