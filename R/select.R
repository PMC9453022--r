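#' Iterative pairwise absolute-correlation pruning
#'
#' While any retained pair of features has absolute Pearson correlation
#' above the threshold, the most-correlated offending pair is examined and
#' the member with the larger mean absolute correlation against all other
#' retained features is dropped (ties break toward dropping the earlier
#' column). Means are recomputed over the retained set after every removal,
#' so on exit no retained pair exceeds the threshold.
#'
#' @param feature_matrix numeric matrix (subjects x features) or a
#'   `feature_table`.
#' @param threshold absolute-correlation cutoff in (0, 1]; 0.75 by default.
#' @param iterative if `FALSE`, a single-pass variant is used: offending
#'   pairs are ranked once on the initial correlation matrix and removals
#'   are applied without recomputation.
#' @return character vector of kept feature names (original column order).
#' @export
correlation_prune <- function(feature_matrix, threshold = 0.75,
                              iterative = TRUE) {
  x <- if (inherits(feature_matrix, "feature_table")) feature_matrix$matrix
       else as.matrix(feature_matrix)
  if (ncol(x) < 2L) stopf("need at least 2 features")
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stopf("`threshold` must lie in (0, 1]")
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("feature_%02d", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant feature column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))

  r <- abs(stats::cor(x))
  diag(r) <- 0
  keep <- seq_len(ncol(x))

  drop_of_pair <- function(rsub, i, j) {
    ## mean |r| of each member against the other retained features
    mi <- mean(rsub[i, -i])
    mj <- mean(rsub[j, -j])
    if (mi > mj) i else if (mj > mi) j else min(i, j)
  }

  if (iterative) {
    repeat {
      rsub <- r[keep, keep, drop = FALSE]
      if (length(keep) < 2L || max(rsub) <= threshold) break
      ij <- which(rsub == max(rsub), arr.ind = TRUE)[1, ]
      keep <- keep[-drop_of_pair(rsub, min(ij), max(ij))]
    }
  } else {
    rsub <- r[keep, keep, drop = FALSE]
    ord <- which(upper.tri(rsub) & rsub > threshold, arr.ind = TRUE)
    if (nrow(ord)) {
      ord <- ord[order(-rsub[ord]), , drop = FALSE]
      dropped <- logical(ncol(x))
      for (k in seq_len(nrow(ord))) {
        i <- ord[k, 1]; j <- ord[k, 2]
        if (dropped[i] || dropped[j]) next
        dropped[drop_of_pair(rsub, i, j)] <- TRUE
      }
      keep <- keep[!dropped[keep]]
    }
  }
  colnames(x)[sort(keep)]
}

#' The log-spaced L1 penalty grid
#'
#' 46 penalty values from 1e-6 to 1e3, consecutive values differing by a
#' factor of 10^0.2.
#'
#' @return increasing numeric vector of length 46.
#' @export
make_alpha_grid <- function() {
  10^seq(-6, 3, length.out = 46L)
}

#' L1-penalized selection with cross-validated penalty choice
#'
#' Fits an L1-penalized model over the alpha grid and picks the penalty by
#' stratified k-fold cross-validation scored with the mean squared error
#' between the predicted class-1 (MCI) probability and the 0/1 label
#' (for `mode = "linear"`, the linear prediction on 0/1 labels).
#' Ties in CV MSE resolve toward the larger penalty (sparser model). The
#' model is then refit on all data at the chosen penalty and features with
#' coefficient magnitude above 1e-8 are reported.
#'
#' Features are z-standardized before penalization so the penalty treats all
#' regions equitably; inside CV the standardization is learned on the
#' training folds only.
#'
#' @param feature_matrix numeric matrix (subjects x features) or a
#'   `feature_table` (in which case `labels` is taken from it).
#' @param labels per-subject class (`"MCI"`/`"nMCI"`, factor, or 0/1 with
#'   1 = MCI).
#' @param alpha_grid penalty grid; defaults to [make_alpha_grid()]. Alpha is
#'   the `lambda` of the penalized objective `-loglik/n + alpha * ||beta||_1`
#'   (or `RSS/(2n) + alpha * ||beta||_1` in linear mode).
#' @param n_folds folds for CV (must not exceed the smaller class count).
#' @param seed integer seed controlling fold assignment.
#' @param mode `"logistic"` (L1 logistic, default) or `"linear"` (lasso on
#'   the 0/1 labels).
#' @return an object of class `selection_result`: `kept_after_prune` is
#'   `colnames(feature_matrix)` as given (pruning is a separate step —
#'   see [correlation_prune()]), `alpha_grid`, `cv_mse_per_alpha`,
#'   `best_alpha`, `nonzero_features` (named coefficient vector on the
#'   standardized scale), `seed`, `mode`.
#' @export
lasso_select <- function(feature_matrix, labels = NULL,
                         alpha_grid = make_alpha_grid(), n_folds = 10L,
                         seed = 1L, mode = c("logistic", "linear")) {
  mode <- match.arg(mode)
  if (inherits(feature_matrix, "feature_table")) {
    labels <- labels %||% feature_matrix$labels
    feature_matrix <- feature_matrix$matrix
  }
  x <- as.matrix(feature_matrix)
  if (!ncol(x)) stopf("empty feature set")
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("feature_%02d", seq_len(ncol(x)))
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L) stopf("labels contain a single class")
  if (n_folds > min(table(y)))
    stopf("`n_folds` exceeds the smaller class count")
  if (any(!is.finite(alpha_grid)) || any(alpha_grid <= 0))
    stopf("alpha grid must be positive and finite")

  lam_desc <- sort(unique(alpha_grid), decreasing = TRUE)
  family <- if (mode == "logistic") "binomial" else "gaussian"
  ## short grids get warm-up penalties prepended so the coordinate-descent
  ## path starts from the fully shrunk model (predictions/coefficients are
  ## still read off at the requested penalties only)
  fit_lambdas <- if (length(lam_desc) < 5)
    sort(unique(c(lam_desc, max(lam_desc, 1) * 10^(1:4))), decreasing = TRUE)
  else lam_desc

  folds <- make_stratified_folds(y, n_folds, seed)
  sqerr <- matrix(NA_real_, nrow(x), length(lam_desc))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    std <- fit_standardizer(x[tr, , drop = FALSE])
    xt <- apply_standardizer(std, x[tr, , drop = FALSE])
    xv <- apply_standardizer(std, x[!tr, , drop = FALSE])
    fit <- quiet_small_n(
      glmnet::glmnet(xt, y[tr], family = family, alpha = 1,
                     lambda = fit_lambdas, standardize = FALSE))
    pred <- predict(fit, xv, type = "response", s = lam_desc, exact = FALSE)
    sqerr[!tr, ] <- (pred - y[!tr])^2
  }
  cv_mse_desc <- colMeans(sqerr)
  ## ties -> larger alpha = earlier index in the descending sequence
  best_idx <- which(cv_mse_desc <= min(cv_mse_desc) + 0)[1]
  best_alpha <- lam_desc[best_idx]

  std <- fit_standardizer(x)
  fit <- quiet_small_n(
    glmnet::glmnet(apply_standardizer(std, x), y, family = family,
                   alpha = 1, lambda = fit_lambdas, standardize = FALSE))
  beta <- as.numeric(stats::coef(fit, s = best_alpha, exact = FALSE))[-1]
  names(beta) <- colnames(x)
  nz <- beta[abs(beta) > 1e-8]

  ## report MSE in the (ascending) order of the requested grid
  ord <- match(sort(unique(alpha_grid)), lam_desc)
  structure(list(kept_after_prune = colnames(x),
                 alpha_grid = sort(unique(alpha_grid)),
                 cv_mse_per_alpha = cv_mse_desc[ord],
                 best_alpha = best_alpha,
                 nonzero_features = nz,
                 seed = as.integer(seed), mode = mode),
            class = "selection_result")
}

as_binary_label <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stopf("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("MCI", "nMCI")))
    stopf("labels must be 'MCI'/'nMCI' or 0/1")
  as.numeric(labels == "MCI")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> best alpha %.3g (CV MSE %.4f); %d nonzero of %d features\n",
    x$best_alpha, min(x$cv_mse_per_alpha), length(x$nonzero_features),
    length(x$kept_after_prune)))
  if (length(x$nonzero_features)) {
    co <- sort(x$nonzero_features, decreasing = TRUE)
    cat(paste(sprintf("  %-24s %+.4f", names(co), co), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Two-stage feature selection: pruning then penalized selection
#'
#' Convenience wrapper running [correlation_prune()] followed by
#' [lasso_select()] on the surviving columns.
#'
#' @inheritParams lasso_select
#' @param prune_threshold absolute-correlation cutoff for the pruning stage.
#' @return a `selection_result` whose `kept_after_prune` reflects the prune.
#' @export
select_features <- function(feature_matrix, labels = NULL,
                            prune_threshold = 0.75,
                            alpha_grid = make_alpha_grid(), n_folds = 10L,
                            seed = 1L, mode = "logistic") {
  if (inherits(feature_matrix, "feature_table")) {
    labels <- labels %||% feature_matrix$labels
    feature_matrix <- feature_matrix$matrix
  }
  kept <- correlation_prune(feature_matrix, prune_threshold)
  if (!length(kept)) stopf("pruning removed every feature")
  res <- lasso_select(feature_matrix[, kept, drop = FALSE], labels,
                      alpha_grid = alpha_grid, n_folds = n_folds,
                      seed = seed, mode = mode)
  res$kept_after_prune <- kept
  res
}

#' Write a selection result as JSON
#' @param result a `selection_result`.
#' @param path output path.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(list(
    kept_after_prune = result$kept_after_prune,
    alpha_grid = result$alpha_grid,
    cv_mse_per_alpha = result$cv_mse_per_alpha,
    best_alpha = result$best_alpha,
    nonzero_features = as.list(result$nonzero_features),
    seed = result$seed, mode = result$mode
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
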