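features_matrix <- function(features) {
  if (inherits(features, "ixp_features")) features$values
  else if (is.matrix(features)) features
  else as.matrix(features)
}

features_labels <- function(features, labels) {
  if (!is.null(labels)) return(labels)
  if (inherits(features, "ixp_features") && !is.null(features$labels)) {
    return(features$labels)
  }
  rlang::abort("labels must be supplied (none stored with the features)")
}

#' Train a linear-kernel support-vector machine on integrated profiles
#'
#' Thin wrapper around [e1071::svm()] with a linear kernel, `scale = FALSE`
#' and regularization `cost = c_param`. Unscaled features keep the fit
#' exactly permutation-equivariant in the feature columns, so orderings that
#' merely permute positions cannot change predictions.
#'
#' @param features An [ixp_features] object or samples-by-features matrix.
#' @param labels 0/1 vector over the samples (taken from `features` when
#'   stored there); both classes need at least two samples.
#' @param c_param SVM cost parameter, `> 0`.
#' @return A fitted `svm` model.
#' @export
train_classifier <- function(features, labels = NULL, c_param = 1) {
  stopifnot(c_param > 0)
  X <- features_matrix(features)
  y <- features_labels(features, labels)
  if (!is.null(names(y))) y <- y[rownames(X)]
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    rlang::abort("training labels contain a single class")
  }
  if (any(table(y) < 2L)) {
    rlang::abort("each class needs at least 2 training samples")
  }
  if (!all(is.finite(X))) rlang::abort("features must be finite")
  e1071::svm(x = X, y = factor(y, levels = 0:1), kernel = "linear",
             cost = c_param, scale = FALSE)
}

#' Classification accuracy of a fitted model on a labeled feature set
#'
#' @param model Model from [train_classifier()].
#' @param features An [ixp_features] object or matrix with the training
#'   dimensionality.
#' @param labels 0/1 vector over the samples (taken from `features` when
#'   stored there).
#' @return Fraction of correctly classified samples in \[0, 1].
#' @export
evaluate_accuracy <- function(model, features, labels = NULL) {
  X <- features_matrix(features)
  y <- features_labels(features, labels)
  if (!is.null(names(y))) y <- y[rownames(X)]
  n_train_feat <- ncol(model$SV)
  if (ncol(X) != n_train_feat) {
    rlang::abort(sprintf("feature dimension mismatch: model expects %d, got %d",
                         n_train_feat, ncol(X)))
  }
  pred <- stats::predict(model, X)
  mean(as.integer(as.character(pred)) == as.integer(y))
}

sweep_methods <- c("acor", "rank", "hclust", "random", "random_uniweight")

#' Train/test accuracy sweep over orderings and influence coefficients
#'
#' Reproduces the benchmarking protocol: for each ordering method the node
#' ordering is computed once from the network alone (never from test data),
#' gene weights are derived from network degree (uniform for the
#' `random_uniweight` baseline, which reuses the same permutation as
#' `random`), and for every `r` in the grid the train and test sets are
#' transformed, a linear SVM is fitted on the training features, and its
#' accuracy on the test set is recorded.
#'
#' @param train,test [expression_set] objects with two-class labels.
#' @param net A connected [ppi_network].
#' @param r_grid Influence coefficients to sweep (default 0 to 0.9 by 0.1).
#' @param methods Subset of `"acor"`, `"rank"`, `"hclust"`, `"random"`,
#'   `"random_uniweight"`.
#' @param seed Seed for the stochastic orderings.
#' @param acor [acor_params] for the ant-colony ordering.
#' @param base_bandwidth Positions per unit of `r`.
#' @param weight_mode Weight mode for all non-uniweight methods.
#' @param normalization Passed to [transform_dataset()].
#' @param c_param SVM cost.
#' @param feature_scaling `"kernel_norm"` (default) divides the train and
#'   test feature matrices by [kernel_l2_norm()] — a single scalar per `r`,
#'   equal to 1 at `r = 0` — so the fixed-cost SVM sees comparable feature
#'   scales along the sweep; `"none"` feeds the raw integrated profiles.
#' @return An `ixp_sweep` tibble with columns `method`, `r`, `accuracy`
#'   (complete grid) and a `meta` attribute recording sizes and settings.
#' @export
run_sweep <- function(train, test, net,
                      r_grid = seq(0, 0.9, by = 0.1),
                      methods = c("acor", "rank", "hclust", "random",
                                  "random_uniweight"),
                      seed = 1L, acor = acor_params(),
                      base_bandwidth = 10,
                      weight_mode = c("degree", "uniform"),
                      normalization = c("per_gene_z", "none"),
                      c_param = 1,
                      feature_scaling = c("kernel_norm", "none")) {
  weight_mode <- match.arg(weight_mode)
  normalization <- match.arg(normalization)
  feature_scaling <- match.arg(feature_scaling)
  stopifnot(length(r_grid) >= 1L, all(r_grid >= 0 & r_grid < 1))
  methods <- match.arg(methods, choices = sweep_methods, several.ok = TRUE)
  if (length(intersect(rownames(train$values), net$genes)) == 0L ||
      length(intersect(rownames(test$values), net$genes)) == 0L) {
    rlang::abort("train and test must share at least one gene with the network")
  }

  base_methods <- unique(sub("_uniweight$", "", methods))
  orderings <- stats::setNames(
    lapply(base_methods, function(m) compute_ordering(net, m, seed = seed, acor = acor)),
    base_methods)
  w_main <- compute_gene_weights(net, mode = weight_mode)
  w_uni <- compute_gene_weights(net, mode = "uniform")

  grid <- tidyr::expand_grid(method = methods, r = r_grid)
  acc <- purrr::pmap_dbl(grid, function(method, r) {
    base <- sub("_uniweight$", "", method)
    ord <- orderings[[base]]
    w <- if (grepl("_uniweight$", method)) w_uni else w_main
    params <- ixp_params(r = r, base_bandwidth = base_bandwidth,
                         weight_mode = attr(w, "mode"))
    tryCatch({
      ftr <- transform_dataset(train, ord, w, params, normalization)
      fte <- transform_dataset(test, ord, w, params, normalization)
      k <- if (feature_scaling == "kernel_norm") {
        kernel_l2_norm(r, nrow(ord), base_bandwidth)
      } else 1
      model <- train_classifier(ftr$values / k, ftr$labels, c_param = c_param)
      evaluate_accuracy(model, fte$values / k, fte$labels)
    }, error = function(e) {
      rlang::abort(sprintf("sweep failed at method=%s, r=%g: %s",
                           method, r, conditionMessage(e)))
    })
  })
  out <- dplyr::bind_cols(grid, tibble::tibble(accuracy = acc))
  attr(out, "meta") <- list(n_train = ncol(train$values),
                            n_test = ncol(test$values),
                            n_genes = length(net$genes),
                            seed = seed,
                            base_bandwidth = base_bandwidth,
                            weight_mode = weight_mode,
                            normalization = normalization,
                            c_param = c_param,
                            feature_scaling = feature_scaling)
  class(out) <- c("ixp_sweep", class(out))
  out
}

#' Write a sweep result as a long-format TSV
#'
#' @param sweep An `ixp_sweep` tibble.
#' @param path Output path. A `#` provenance header records the settings.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  meta <- attr(sweep, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# ixp_sweep %s",
                       paste(sprintf("%s=%s", names(meta),
                                     vapply(meta, format, "")),
                             collapse = " ")), con)
  }
  writeLines("method\tr\taccuracy", con)
  writeLines(sprintf("%s\t%s\t%s", sweep$method,
                     format(sweep$r, digits = 17, trim = TRUE),
                     format(sweep$accuracy, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @method tidy ixp_sweep
#' @export
tidy.ixp_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an accuracy sweep
#'
#' @param x An `ixp_sweep` tibble.
#' @param ... Unused.
#' @return Tibble with the best cell (method, r, accuracy) and the
#'   `r = 0` reference accuracy (identical across methods under uniform
#'   weights).
#' @method glance ixp_sweep
#' @export
glance.ixp_sweep <- function(x, ...) {
  best <- x[order(-x$accuracy, x$r, x$method), ][1L, ]
  r0 <- x$accuracy[x$r == 0]
  tibble::tibble(best_method = best$method, best_r = best$r,
                 best_accuracy = best$accuracy,
                 r0_accuracy = if (length(r0)) mean(r0) else NA_real_)
}
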