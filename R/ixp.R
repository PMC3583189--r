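#' Parameters of the integrative expression transform
#'
#' @param r Horizontal influence coefficient in \[0, 1): controls how far a
#'   gene's expression spreads along the ordering. `r = 0` gives a delta
#'   kernel, i.e. the raw weighted profile.
#' @param base_bandwidth Positions per unit of `r`; the Gaussian width is
#'   `sigma = r * base_bandwidth`.
#' @param weight_mode Gene weight mode used when weights are derived from a
#'   network (`"degree"` or `"uniform"`).
#' @param missing_expression_value Value substituted for network genes absent
#'   from the expression data (default 0, i.e. no contribution after
#'   centering).
#' @return A list of class `ixp_params`.
#' @export
ixp_params <- function(r = 0, base_bandwidth = 10,
                       weight_mode = c("degree", "uniform"),
                       missing_expression_value = 0) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(r >= 0, r < 1, base_bandwidth > 0)
  structure(list(r = r, base_bandwidth = base_bandwidth,
                 weight_mode = weight_mode,
                 missing_expression_value = missing_expression_value),
            class = "ixp_params")
}

#' Gaussian influence of a gene at a positional offset
#'
#' `exp(-delta^2 / (2 sigma^2))` for `sigma > 0`; the `sigma = 0` limit is
#' the delta kernel (1 at offset 0, else 0).
#'
#' @param delta Positional offset(s), in ordering positions.
#' @param sigma Kernel width in positions, `>= 0`.
#' @return Influence value(s) in \[0, 1].
#' @examples
#' gaussian_influence(2, 2)  # exp(-1/2)
#' @export
gaussian_influence <- function(delta, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(as.numeric(delta == 0))
  exp(-delta^2 / (2 * sigma^2))
}

#' Global L2 norm of the Gaussian influence kernel
#'
#' `sqrt(sum_d gaussian_influence(d, sigma)^2)` over all offsets an axis of
#' `n` positions can realise; equals 1 at `sigma = 0`. Dividing a feature
#' matrix by this scalar keeps feature magnitudes comparable across the `r`
#' sweep without touching the relative shape of any profile (the classifier
#' otherwise sees a fixed-cost SVM whose effective regularization drifts
#' with `r`).
#'
#' @param r Horizontal influence coefficient.
#' @param n Number of ordering positions.
#' @param base_bandwidth Positions per unit of `r`.
#' @return A positive scalar.
#' @export
kernel_l2_norm <- function(r, n, base_bandwidth = 10) {
  sigma <- r * base_bandwidth
  if (sigma == 0) return(1)
  d <- seq.int(-(n - 1L), n - 1L)
  sqrt(sum(gaussian_influence(d, sigma)^2))
}

#' Total mass (L1 norm) of the Gaussian influence kernel
#'
#' `sum_d gaussian_influence(d, sigma)`; 1 at `sigma = 0`. Dividing an
#' integrated profile by this mass yields the per-unit-mass (moving-average
#' style) view of the smoothing, on which total variation is non-increasing
#' in `r`; the raw profile's amplitude instead grows with the kernel mass by
#' design (the additive peak effect).
#'
#' @inheritParams kernel_l2_norm
#' @return A positive scalar.
#' @export
kernel_l1_norm <- function(r, n, base_bandwidth = 10) {
  sigma <- r * base_bandwidth
  if (sigma == 0) return(1)
  d <- seq.int(-(n - 1L), n - 1L)
  sum(gaussian_influence(d, sigma))
}

# positions x genes kernel matrix K[i, j] = influence of the gene at
# position j on position i; Toeplitz in (i - j).
influence_kernel <- function(n, sigma) {
  if (sigma == 0) return(diag(n))
  d <- seq_len(n) - 1L
  col1 <- gaussian_influence(d, sigma)
  stats::toeplitz(col1)
}

#' Integrate one expression profile along a node ordering
#'
#' The integrated profile at position `i` is the weighted superposition
#' `F(i) = sum_g w(g) x(g) exp(-(i - pos(g))^2 / (2 sigma^2))` with
#' `sigma = r * base_bandwidth`; at `r = 0` it reduces exactly to the
#' weighted expression vector permuted into position order. Genes in the
#' ordering but absent from `expr` contribute
#' `missing_expression_value`; genes in `expr` but not in the ordering are
#' counted and ignored. The kernel is deliberately not renormalized, so
#' several adjacent weakly-shifted genes superpose into a peak that can
#' exceed an isolated strong gene's.
#'
#' @param expr Named numeric vector, gene -> expression value.
#' @param ord A node ordering.
#' @param weights Gene-weight tibble from [compute_gene_weights()], covering
#'   the ordering's genes.
#' @param params An [ixp_params] list.
#' @return Numeric vector of length `N` (positions 1..N), with attribute
#'   `n_unmapped` (genes in `expr` missing from the ordering).
#' @export
integrate_profile <- function(expr, ord, weights, params = ixp_params()) {
  stopifnot(is.numeric(expr), !is.null(names(expr)))
  w <- stats::setNames(weights$weight, weights$gene)
  if (!all(ord$gene %in% names(w))) {
    rlang::abort("weights do not cover the ordering's genes")
  }
  n <- nrow(ord)
  genes_by_pos <- ord$gene[order(ord$position)]
  x <- expr[genes_by_pos]
  n_unmapped <- sum(!names(expr) %in% ord$gene)
  x[is.na(x)] <- params$missing_expression_value
  xw <- unname(w[genes_by_pos] * x)
  sigma <- params$r * params$base_bandwidth
  out <- if (sigma == 0) xw else as.numeric(influence_kernel(n, sigma) %*% xw)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

new_ixp_features <- function(values, provenance, labels = NULL, classes = NULL) {
  structure(list(values = values, provenance = provenance,
                 labels = labels, classes = classes),
            class = "ixp_features")
}

#' @export
print.ixp_features <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<ixp_features> %d samples x %d positions (method=%s, r=%g, weights=%s, norm=%s)\n",
              nrow(x$values), ncol(x$values), p$method, p$r, p$weight_mode,
              p$normalization))
  invisible(x)
}

#' Transform an expression dataset into integrated feature profiles
#'
#' Optionally standardizes each gene across the dataset's samples
#' (`per_gene_z`: mean 0, sd 1; zero-variance genes map to 0), then applies
#' [integrate_profile()] to every sample. Standardization is always computed
#' within the given dataset, so train and test sets are standardized
#' independently — the cross-platform transfer setting.
#'
#' @param em An [expression_set].
#' @param ord A node ordering.
#' @param weights Gene-weight tibble covering the ordering's genes.
#' @param params An [ixp_params] list.
#' @param normalization `"per_gene_z"` (default) or `"none"`.
#' @return An [ixp_features] object: samples-by-positions matrix plus
#'   provenance `(method, r, weight_mode, base_bandwidth, normalization)`;
#'   sample labels are carried through when present.
#' @export
transform_dataset <- function(em, ord, weights, params = ixp_params(),
                              normalization = c("per_gene_z", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(em, "expression_set"), ncol(em$values) >= 1L)
  shared <- intersect(rownames(em$values), ord$gene)
  if (length(shared) == 0L) {
    rlang::abort("no genes shared between the expression data and the ordering")
  }
  X <- em$values
  if (normalization == "per_gene_z") {
    mu <- rowMeans(X)
    sdv <- apply(X, 1L, stats::sd)
    X <- (X - mu) / ifelse(sdv == 0, 1, sdv)
    X[sdv == 0, ] <- 0
  }
  n <- nrow(ord)
  genes_by_pos <- ord$gene[order(ord$position)]
  w <- stats::setNames(weights$weight, weights$gene)
  if (!all(genes_by_pos %in% names(w))) {
    rlang::abort("weights do not cover the ordering's genes")
  }
  # genes-in-position-order x samples, missing genes filled
  Xp <- matrix(params$missing_expression_value, n, ncol(X),
               dimnames = list(genes_by_pos, colnames(X)))
  hit <- genes_by_pos %in% rownames(X)
  Xp[hit, ] <- X[genes_by_pos[hit], , drop = FALSE]
  Xw <- unname(w[genes_by_pos]) * Xp
  sigma <- params$r * params$base_bandwidth
  Fm <- if (sigma == 0) Xw else influence_kernel(n, sigma) %*% Xw
  values <- t(Fm)
  colnames(values) <- sprintf("P%d", seq_len(n))
  new_ixp_features(values,
                   provenance = list(method = ordering_method(ord) %||% "unknown",
                                     r = params$r,
                                     weight_mode = attr(weights, "mode") %||% params$weight_mode,
                                     base_bandwidth = params$base_bandwidth,
                                     normalization = normalization),
                   labels = em$labels, classes = em$classes)
}

#' Tidy integrated features into a long tibble
#'
#' @param x An [ixp_features] object.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `position`, `value` and, when labels
#'   are present, `class`.
#' @method tidy ixp_features
#' @export
tidy.ixp_features <- function(x, ...) {
  out <- tibble::tibble(
    sample = rep(rownames(x$values), times = ncol(x$values)),
    position = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values))
  if (!is.null(x$labels)) {
    out$class <- x$classes[x$labels[out$sample] + 1L]
  }
  out
}

#' Average integrated profile per class
#'
#' @param fm An [ixp_features] object.
#' @param labels Optional named 0/1 vector overriding the labels stored in
#'   `fm`; every sample must be labeled and both classes non-empty.
#' @return Tibble with columns `class`, `position`, `value` (the class mean
#'   profile), one row per class and position.
#' @export
group_average_profile <- function(fm, labels = NULL) {
  stopifnot(inherits(fm, "ixp_features"))
  labels <- labels %||% fm$labels
  if (is.null(labels)) rlang::abort("no sample labels available")
  labels <- labels[rownames(fm$values)]
  if (anyNA(labels)) rlang::abort("every sample must be labeled")
  classes <- fm$classes %||% c("0", "1")
  missing_k <- setdiff(0:1, labels)
  if (length(missing_k) > 0L) {
    rlang::abort(sprintf("class '%s' has no samples", classes[missing_k[1L] + 1L]))
  }
  purrr::map_dfr(0:1, function(k) {
    rows <- fm$values[labels == k, , drop = FALSE]
    tibble::tibble(class = classes[k + 1L],
                   position = seq_len(ncol(fm$values)),
                   value = unname(colMeans(rows)))
  })
}
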