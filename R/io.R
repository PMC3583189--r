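#' Read a protein-interaction edge list
#'
#' Reads a tab-separated edge list with two columns (`gene_a`, `gene_b`) or
#' three (`gene_a`, `gene_b`, `confidence`). Gene symbols are canonicalized to
#' upper case with surrounding whitespace stripped. Self-interactions are
#' dropped, duplicate unordered pairs are collapsed keeping the maximum
#' confidence, and edges below `min_confidence` are removed.
#'
#' @param path Path to a tab-separated edge list. A header line is detected
#'   (and skipped) when the third field of the first line is non-numeric
#'   while later lines are numeric, or when the first line equals the
#'   canonical header `gene_a  gene_b  confidence`.
#' @param min_confidence Keep edges with confidence at or above this value.
#'   A confidence column that is absent defaults to 1.0 per edge.
#' @return A tibble with columns `gene_a`, `gene_b`, `confidence`, sorted by
#'   the (canonical, `gene_a < gene_b`) pair so that the result does not
#'   depend on input line order. The number of dropped self-loops is attached
#'   as attribute `n_self_loops`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\t0.9", "B\tA\t0.7", "C\tC\t1.0"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path, min_confidence = 0) {
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1L,
            min_confidence >= 0, min_confidence <= 1)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    rlang::abort(sprintf("no edges: '%s' contains no data lines", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(2L, 3L)))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "parse error at line %d of '%s': expected 2 or 3 tab-separated columns, found %d",
      bad[1L], path, ncols[bad[1L]]))
  }
  # header detection: canonical names, or a non-numeric third field on line 1
  is_header <- FALSE
  f1 <- trimws(fields[[1L]])
  if (identical(tolower(f1[1:2]), c("gene_a", "gene_b"))) {
    is_header <- TRUE
  } else if (length(f1) == 3L && is.na(suppressWarnings(as.numeric(f1[3L]))) &&
             length(fields) > 1L) {
    is_header <- TRUE
  }
  if (is_header) {
    fields <- fields[-1L]
    if (length(fields) == 0L) {
      rlang::abort(sprintf("no edges: '%s' contains only a header", path))
    }
  }
  ga <- toupper(trimws(vapply(fields, `[`, "", 1L)))
  gb <- toupper(trimws(vapply(fields, `[`, "", 2L)))
  conf <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) return(1.0)
    v <- suppressWarnings(as.numeric(trimws(f[3L])))
    if (is.na(v)) {
      rlang::abort(sprintf(
        "parse error at line %d of '%s': confidence '%s' is not numeric",
        i + is_header, path, trimws(f[3L])))
    }
    v
  }, numeric(1))
  if (any(conf < 0 | conf > 1)) {
    rlang::abort("confidence values must lie in [0, 1]")
  }

  self <- ga == gb
  n_self <- sum(self)
  ga <- ga[!self]; gb <- gb[!self]; conf <- conf[!self]
  if (length(ga) == 0L) {
    rlang::abort(sprintf("no edges: every record in '%s' was a self-loop", path))
  }

  # canonical unordered pair, collapse duplicates keeping max confidence
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  edges <- tibble::tibble(gene_a = lo, gene_b = hi, confidence = conf) |>
    dplyr::summarise(confidence = max(.data$confidence),
                     .by = c("gene_a", "gene_b")) |>
    dplyr::filter(.data$confidence >= min_confidence) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  if (nrow(edges) == 0L) {
    rlang::abort(sprintf(
      "no edges: all records in '%s' were self-loops or fell below min_confidence = %g",
      path, min_confidence))
  }
  attr(edges, "n_self_loops") <- n_self
  edges
}

#' Write an edge list to a tab-separated file
#'
#' @param edges Tibble with columns `gene_a`, `gene_b` and optionally
#'   `confidence`; [ppi_network] objects are also accepted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "ppi_network")) edges <- edges$edges
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  conf <- if ("confidence" %in% names(edges)) edges$confidence else rep(1, nrow(edges))
  writeLines(sprintf("%s\t%s\t%s", edges$gene_a, edges$gene_b,
                     format(conf, digits = 17, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a seed-gene list
#'
#' Two tab-separated columns: gene symbol and seed class (`I` or `II`).
#' A single-column file is read as all-class-`I` seeds.
#'
#' @param path Path to the seed file.
#' @return Tibble with columns `gene` (upper-cased) and `class`.
#' @export
read_seed_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) rlang::abort(sprintf("'%s' contains no seed genes", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(fields[[1L]][1L])), "gene")) fields <- fields[-1L]
  gene <- toupper(trimws(vapply(fields, `[`, "", 1L)))
  klass <- vapply(fields, function(f) if (length(f) >= 2L) trimws(f[2L]) else "I", "")
  if (!all(klass %in% c("I", "II"))) {
    rlang::abort("seed class must be 'I' or 'II'")
  }
  tibble::tibble(gene = gene, class = klass) |> dplyr::distinct()
}

#' Read a gene-by-sample expression matrix with two-class sample labels
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and gene/probe symbols in the first column (the common series-matrix-like
#' layout). The label file has two tab-separated columns, sample and class
#' name; exactly two class names must occur. Classes are encoded 0/1 in order
#' of first appearance in the label file unless `class_levels` overrides it
#' (first level becomes 0).
#'
#' Duplicate gene rows (multiple probes per symbol) are collapsed with
#' `collapse` (arithmetic mean by default).
#'
#' @param path Expression matrix path.
#' @param label_path Sample-label path.
#' @param collapse Collapse policy for duplicate gene rows.
#' @param class_levels Optional length-2 character vector fixing the class
#'   encoding (first element encoded 0).
#' @return An [expression_set] object.
#' @export
read_expression <- function(path, label_path,
                            collapse = c("mean", "median", "max"),
                            class_levels = NULL) {
  collapse <- match.arg(collapse)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) rlang::abort(sprintf("'%s' has no data rows", path))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- trimws(header[-1L])
  if (anyDuplicated(sample_ids)) rlang::abort("duplicate sample identifiers in header")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- length(sample_ids) + 1L
  genes <- character(length(rows))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != nc) {
      rlang::abort(sprintf(
        "parse error at data row %d of '%s': expected %d columns, found %d",
        i, path, nc, length(f)))
    }
    genes[i] <- toupper(trimws(f[1L]))
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      rlang::abort(sprintf(
        "parse error in '%s': non-numeric value '%s' at data row %d (gene %s), sample column %d (%s)",
        path, f[j + 1L], i, genes[i], j, sample_ids[j]))
    }
    vals[i, ] <- v
  }

  if (anyDuplicated(genes)) {
    fun <- switch(collapse, mean = mean, median = stats::median, max = max)
    split_idx <- split(seq_along(genes), genes)
    ug <- names(split_idx)
    vals <- t(vapply(split_idx, function(ix) {
      if (length(ix) == 1L) vals[ix, ] else apply(vals[ix, , drop = FALSE], 2L, fun)
    }, numeric(length(sample_ids))))
    genes <- ug
  }
  ord <- order(genes)
  vals <- vals[ord, , drop = FALSE]
  genes <- genes[ord]
  rownames(vals) <- genes
  colnames(vals) <- sample_ids

  lab <- read_labels(label_path, class_levels = class_levels)
  missing <- setdiff(sample_ids, lab$sample)
  if (length(missing) > 0L) {
    rlang::abort(sprintf("sample(s) missing from label file: %s",
                         paste(missing, collapse = ", ")))
  }
  labels <- lab$label[match(sample_ids, lab$sample)]
  names(labels) <- sample_ids
  expression_set(vals, labels, classes = attr(lab, "classes"))
}

read_labels <- function(label_path, class_levels = NULL) {
  lines <- readLines(label_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(fields[[1L]][1L])), "sample")) fields <- fields[-1L]
  if (any(lengths(fields) < 2L)) {
    rlang::abort(sprintf("label file '%s': every line needs sample\\tclass", label_path))
  }
  sample <- trimws(vapply(fields, `[`, "", 1L))
  klass <- trimws(vapply(fields, `[`, "", 2L))
  classes <- if (is.null(class_levels)) unique(klass) else class_levels
  if (length(classes) != 2L || !all(klass %in% classes)) {
    rlang::abort(sprintf(
      "label file '%s' must define exactly two classes (found: %s)",
      label_path, paste(unique(klass), collapse = ", ")))
  }
  out <- tibble::tibble(sample = sample,
                        label = as.integer(match(klass, classes) - 1L))
  attr(out, "classes") <- classes
  out
}

#' Construct an expression set
#'
#' Container for a genes-by-samples expression matrix with optional 0/1
#' sample labels.
#'
#' @param values Numeric matrix, genes in rows (rownames) and samples in
#'   columns (colnames).
#' @param labels Optional named integer vector (0/1) over the samples.
#' @param classes Optional length-2 character vector naming the classes
#'   encoded 0 and 1.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, labels = NULL, classes = c("0", "1")) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) rlang::abort("gene identifiers must be unique")
  if (!is.null(labels)) {
    if (is.null(names(labels))) names(labels) <- colnames(values)
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing) > 0L) {
      rlang::abort(sprintf("sample(s) without a label: %s",
                           paste(missing, collapse = ", ")))
    }
    labels <- as.integer(labels[colnames(values)])
    stopifnot(all(labels %in% c(0L, 1L)))
    names(labels) <- colnames(values)
  }
  structure(list(values = values, labels = labels, classes = classes),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:1, labels = x$classes))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Tidy an expression set into a long tibble
#'
#' @param x An [expression_set].
#' @param ... Unused.
#' @return Tibble with columns `gene`, `sample`, `value` and, when labels are
#'   present, `class`.
#' @method tidy expression_set
#' @export
tidy.expression_set <- function(x, ...) {
  out <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values))
  if (!is.null(x$labels)) {
    out$class <- x$classes[x$labels[out$sample] + 1L]
  }
  out
}

#' Write an expression set as matrix + label files
#'
#' @param em An [expression_set] with labels.
#' @param path Matrix output path.
#' @param label_path Label output path (omit to skip labels).
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, label_path = NULL) {
  stopifnot(inherits(em, "expression_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(em$values)), collapse = "\t"), con)
  body <- apply(em$values, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(em$values), body, sep = "\t"), con)
  if (!is.null(label_path)) {
    if (is.null(em$labels)) rlang::abort("expression set has no labels to write")
    writeLines(c("sample\tclass",
                 paste(names(em$labels), em$classes[em$labels + 1L], sep = "\t")),
               label_path)
  }
  invisible(path)
}

#' Write a node ordering as a two-column file
#'
#' @param ord A node ordering tibble (`gene`, `position`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordering <- function(ord, path) {
  stopifnot(all(c("gene", "position") %in% names(ord)))
  o <- ord[order(ord$position), ]
  writeLines(sprintf("%s\t%d", o$gene, as.integer(o$position)), path)
  invisible(path)
}

#' Read a node ordering written by [write_ordering()]
#'
#' @param path Input path.
#' @param method Method tag to attach (recorded provenance only).
#' @return A `node_ordering` tibble.
#' @export
read_ordering <- function(path, method = "file") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    rlang::abort(sprintf("'%s': every line must be gene\\tposition", path))
  }
  gene <- toupper(trimws(vapply(fields, `[`, "", 1L)))
  pos <- as.integer(vapply(fields, `[`, "", 2L))
  ord <- tibble::tibble(gene = gene, position = pos) |>
    dplyr::arrange(.data$position)
  validate_ordering_tbl(ord)
  new_node_ordering(ord$gene, method = method)
}

#' Write an integrated feature matrix
#'
#' Samples-by-positions TSV with a `#`-prefixed provenance header recording
#' the ordering method, influence coefficient, weight mode, bandwidth and
#' normalization.
#'
#' @param fm An [ixp_features] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "ixp_features"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- fm$provenance
  writeLines(sprintf("# ixp_features method=%s r=%s weight_mode=%s base_bandwidth=%s normalization=%s",
                     p$method, format(p$r, digits = 17),
                     p$weight_mode, format(p$base_bandwidth, digits = 17),
                     p$normalization), con)
  writeLines(paste(c("sample", sprintf("P%d", seq_len(ncol(fm$values)))),
                   collapse = "\t"), con)
  body <- apply(fm$values, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(fm$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input path.
#' @return An [ixp_features] object.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  prov <- list(method = NA_character_, r = NA_real_, weight_mode = NA_character_,
               base_bandwidth = NA_real_, normalization = NA_character_)
  hdr <- grep("^# ixp_features", lines, value = TRUE)
  if (length(hdr) == 1L) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1L]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1L]]
      key <- parts[1L]
      if (key %in% c("r", "base_bandwidth")) prov[[key]] <- as.numeric(parts[2L])
      else if (key %in% names(prov)) prov[[key]] <- parts[2L]
    }
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  fields <- fields[-1L]
  samples <- vapply(fields, `[`, "", 1L)
  vals <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                   numeric(length(header) - 1L)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(samples))
  rownames(vals) <- samples
  colnames(vals) <- header[-1L]
  new_ixp_features(vals, provenance = prov, labels = NULL, classes = NULL)
}

#' Export the reordered adjacency matrix
#'
#' Writes the network adjacency with rows and columns permuted into ordering
#' positions, as plotted in seriation heatmaps of reordered interaction
#' matrices.
#'
#' @param net A [ppi_network].
#' @param ord A node ordering covering exactly the network's genes.
#' @param path Output path.
#' @param values `"binary"` writes 0/1, `"confidence"` writes edge confidences.
#' @return `path`, invisibly.
#' @export
write_reordered_adjacency <- function(net, ord, path,
                                      values = c("binary", "confidence")) {
  values <- match.arg(values)
  A <- adjacency_matrix(net, weighted = values == "confidence")
  genes_by_pos <- ord$gene[order(ord$position)]
  if (!setequal(genes_by_pos, rownames(A)) ||
      length(genes_by_pos) != nrow(A)) {
    rlang::abort("ordering does not cover exactly the network's genes")
  }
  A <- A[genes_by_pos, genes_by_pos]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", genes_by_pos), collapse = "\t"), con)
  body <- apply(A, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(genes_by_pos, body, sep = "\t"), con)
  invisible(path)
}
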