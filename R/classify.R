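#' Describe a classifier and its hyperparameter grid
#'
#' @param model `"svm_linear"`, `"random_forest"` or
#'   `"logistic_regression"`.
#' @param grid named list of hyperparameter vectors. Defaults: cost
#'   `C in {0.01, 0.1, 1, 10, 100}` for the linear SVM and the
#'   (L2-regularized) logistic model; `n_trees in {100, 500}` and
#'   `max_depth in {NA, 3, 5}` (NA = unrestricted) for the random forest.
#' @param seed integer seed feeding fold shuffles and forest bootstraps.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = c("svm_linear", "random_forest",
                                 "logistic_regression"),
                       grid = NULL, seed = 1L) {
  model <- match.arg(model)
  if (is.null(grid))
    grid <- switch(model,
      svm_linear = list(C = c(0.01, 0.1, 1, 10, 100)),
      logistic_regression = list(C = c(0.01, 0.1, 1, 10, 100)),
      random_forest = list(n_trees = c(100L, 500L), max_depth = c(NA, 3, 5)))
  if (!length(grid) || !all(lengths(grid) >= 1L))
    stopf("hyperparameter grid must be nonempty")
  structure(list(model = model, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

label_factor <- function(labels) {
  factor(as.character(labels), levels = c("MCI", "nMCI"))
}

## Two glmnet warnings are routine here rather than actionable: the
## small-class caveat (inherent to LOOCV folds on small cohorts) and
## non-convergence at penalties far below machine-relevant shrinkage on
## (quasi-)separable data, where the path solutions at larger penalties
## are returned and used.
quiet_small_n <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8\\s+observations|Convergence for .* lambda value",
              conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

## Fit one model on an already-standardized matrix. `hyper` is one row of
## the expanded grid (a named list).
fit_one <- function(model, x, y, hyper, seed) {
  yf <- label_factor(y)
  switch(model,
    svm_linear = e1071::svm(x, yf, kernel = "linear", cost = hyper$C,
                            scale = FALSE, probability = FALSE),
    logistic_regression = {
      lam <- 1 / (nrow(x) * hyper$C)
      quiet_small_n(
        glmnet::glmnet(x, as.numeric(yf == "MCI"), family = "binomial",
                       alpha = 0, lambda = lam * c(8, 4, 2, 1),
                       standardize = FALSE))
    },
    random_forest = with_seed(seed, {
      maxnodes <- if (is.na(hyper$max_depth)) NULL
        else min(2L^as.integer(hyper$max_depth), nrow(x))
      randomForest::randomForest(x, yf, ntree = as.integer(hyper$n_trees),
                                 maxnodes = maxnodes, importance = FALSE)
    }),
    stopf("unknown model '%s'", model))
}

## Continuous MCI-positive score: signed decision value for the SVM,
## class-MCI probability for the probabilistic models.
score_one <- function(model, fit, xnew, hyper = NULL) {
  switch(model,
    svm_linear = {
      pr <- predict(fit, xnew, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- as.numeric(dv[, 1])
      if (!startsWith(colnames(dv)[1], "MCI")) s <- -s
      s
    },
    logistic_regression = {
      lam <- min(fit$lambda)
      as.numeric(predict(fit, xnew, s = lam, type = "response"))
    },
    random_forest = as.numeric(predict(fit, xnew, type = "prob")[, "MCI"]))
}

hard_label <- function(model, score) {
  thr <- if (model == "svm_linear") 0 else 0.5
  ifelse(score > thr, "MCI", "nMCI")
}

expand_grid_list <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

## Inner stratified k-fold grid search scored by accuracy; ties keep the
## first grid point. Returns the winning hyperparameter list.
inner_grid_search <- function(model, x, y, grid, k = 5L, seed = 1L) {
  combos <- expand_grid_list(grid)
  if (length(combos) == 1L) return(combos[[1]])
  mc <- min(table(y))
  if (mc < 3L) return(combos[[1]])  # cannot keep 2 per class in training
  k <- min(k, mc)
  ## every training split must retain >= 2 members of each class
  while (k < mc && mc - ceiling(mc / k) < 2L) k <- k + 1L
  folds <- make_stratified_folds(y, k, seed)
  acc <- vapply(combos, function(h) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      std <- fit_standardizer(x[tr, , drop = FALSE])
      xt <- apply_standardizer(std, x[tr, , drop = FALSE])
      xv <- apply_standardizer(std, x[!tr, , drop = FALSE])
      fit <- fit_one(model, xt, y[tr], h, seed = derive_seed(seed, f))
      correct <- correct +
        sum(hard_label(model, score_one(model, fit, xv, h)) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  combos[[which.max(acc)]]
}

#' Leave-one-out cross-validated predictions
#'
#' For each subject, the model is fit on the other n - 1 subjects (features
#' standardized on the training subjects only; hyperparameters chosen by an
#' inner stratified 5-fold grid search scored by accuracy) and the held-out
#' subject is predicted. The continuous score is the signed decision value
#' for the SVM and the MCI-class probability otherwise.
#'
#' @param spec a [model_spec()].
#' @param features numeric matrix or `feature_table`.
#' @param labels per-subject `"MCI"`/`"nMCI"` (taken from the
#'   `feature_table` when omitted).
#' @param inner_folds folds of the inner hyperparameter search.
#' @param select_fun optional `function(x, y) -> column names`, applied to
#'   each training split before fitting (per-fold nested feature selection).
#' @return data.frame with columns `truth`, `pred`, `score`, one row per
#'   subject in input order.
#' @export
loocv_predict <- function(spec, features, labels = NULL, inner_folds = 5L,
                          select_fun = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$labels
    features <- features$matrix
  }
  x <- as.matrix(features)
  y <- as.character(labels)
  n <- nrow(x)
  if (n < 4L) stopf("need at least 4 subjects")
  if (length(unique(y)) < 2L) stopf("labels contain a single class")

  score <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    if (!is.null(select_fun)) {
      kept <- select_fun(xt, yt)
      if (!length(kept)) kept <- colnames(xt)  # fall back to all features
      xt <- xt[, kept, drop = FALSE]
    }
    std <- fit_standardizer(xt)
    xts <- apply_standardizer(std, xt)
    hyper <- inner_grid_search(spec$model, xt, yt, spec$grid, k = inner_folds,
                               seed = derive_seed(spec$seed, i))
    fit <- fit_one(spec$model, xts, yt, hyper,
                   seed = derive_seed(spec$seed, 100000L + i))
    xv <- apply_standardizer(std, x[i, colnames(xt), drop = FALSE])
    score[i] <- score_one(spec$model, fit, xv, hyper)
  }
  data.frame(truth = y, pred = hard_label(spec$model, score), score = score,
             stringsAsFactors = FALSE)
}

#' Pooled-score ROC area via the rank (Mann-Whitney) construction
#'
#' AUC over all held-out scores: the Mann-Whitney U statistic of the
#' MCI-group scores divided by `n_pos * n_neg`; ties count one half.
#'
#' @param score numeric scores, larger = more MCI-like.
#' @param truth `"MCI"`/`"nMCI"` per score.
#' @return AUC in \[0, 1\].
#' @export
auc_pooled <- function(score, truth) {
  pos <- truth == "MCI"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stopf("both classes required for AUC")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cohen's kappa from a 2x2 confusion
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (TP + TN)/n` and chance agreement
#' `p_e = [(TP+FP)(TP+FN) + (FN+TN)(FP+TN)] / n^2`. The degenerate case
#' `p_e = 1` is defined as 0.
#'
#' @param tp,fn,fp,tn confusion counts with MCI as the positive class;
#'   alternatively `tp` may be a length-4 vector `(TP, FN, FP, TN)`.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (length(tp) == 4L && is.null(fn)) {
    fn <- tp[2]; fp <- tp[3]; tn <- tp[4]; tp <- tp[1]
  }
  n <- tp + fn + fp + tn
  if (n <= 0) stopf("empty confusion")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Performance metrics from held-out predictions
#'
#' Confusion counts (MCI positive), accuracy, sensitivity, specificity,
#' pooled-score AUC and Cohen's kappa.
#'
#' @param truth,pred `"MCI"`/`"nMCI"` vectors.
#' @param score continuous scores for the ROC (larger = more MCI-like).
#' @return an object of class `model_report` (metrics part).
#' @export
compute_metrics <- function(truth, pred, score) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(unique(truth)) < 2L) stopf("both classes required in `truth`")
  if (any(!is.finite(score))) stopf("scores must be finite")
  tp <- sum(truth == "MCI" & pred == "MCI")
  fn <- sum(truth == "MCI" & pred == "nMCI")
  fp <- sum(truth == "nMCI" & pred == "MCI")
  tn <- sum(truth == "nMCI" & pred == "nMCI")
  n <- length(truth)
  structure(list(
    confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = auc_pooled(score, truth),
    kappa = cohen_kappa(tp, fn, fp, tn),
    n = n), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report>%s n=%d | AUC %.3f acc %.3f sens %.3f spec %.3f kappa %.3f%s\n",
    if (!is.null(x$model)) paste0(" ", x$model) else "", x$n, x$auc,
    x$accuracy, x$sensitivity, x$specificity, x$kappa,
    if (!is.null(x$permutation_p))
      sprintf(" | perm p %.4g (%d perms)", x$permutation_p, x$n_permutations)
    else ""))
  invisible(x)
}

#' Per-feature weights of a fitted model
#'
#' Signed coefficients on the standardized feature scale for the linear SVM
#' (`w = t(coefs) %*% SV`, oriented so positive means MCI-like) and the
#' logistic model; impurity-based importances normalized to sum to one for
#' the random forest.
#'
#' @param model model name as in [model_spec()].
#' @param fit the fitted object from that model.
#' @param feature_names column names of the training matrix.
#' @return named numeric vector.
#' @export
feature_weights <- function(model, fit, feature_names) {
  w <- switch(model,
    svm_linear = {
      if (fit$kernel != 0)
        stopf("feature weights require a linear kernel")
      wv <- as.numeric(t(fit$coefs) %*% fit$SV)
      if (!startsWith(colnames(attr(
            predict(fit, fit$SV[1, , drop = FALSE], decision.values = TRUE),
            "decision.values"))[1], "MCI"))
        wv <- -wv
      wv
    },
    logistic_regression =
      as.numeric(stats::coef(fit, s = min(fit$lambda)))[-1],
    random_forest = {
      imp <- randomForest::importance(fit, type = 2)[, 1]
      imp <- pmax(imp, 0)
      if (sum(imp) > 0) imp / sum(imp) else imp
    })
  names(w) <- feature_names
  w
}

## Shared protocol for observed data and permutations: optional selection,
## then LOOCV, then pooled AUC.
eval_auc_once <- function(spec, x, y, selection_mode, inner_folds,
                          prune_threshold, lasso_folds, lasso_seed) {
  select_all <- function(xx, yy) {
    kept <- tryCatch(correlation_prune(xx, prune_threshold),
                     error = function(e) colnames(xx))
    res <- lasso_select(xx[, kept, drop = FALSE], yy,
                        n_folds = min(lasso_folds, min(table(yy))),
                        seed = lasso_seed)
    names(res$nonzero_features)
  }
  if (selection_mode == "per_permutation") {
    kept <- select_all(x, y)
    if (length(kept)) x <- x[, kept, drop = FALSE]
  }
  sf <- if (selection_mode == "nested") select_all else NULL
  held <- loocv_predict(spec, x, y, inner_folds = inner_folds,
                        select_fun = sf)
  auc_pooled(held$score, held$truth)
}

#' Permutation test of a classifier's pooled-LOOCV AUC
#'
#' The observed statistic is the pooled leave-one-out AUC. For each
#' permutation the labels are shuffled and the full evaluation protocol is
#' re-run; the p-value uses the add-one rule
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (n_permutations + 1)`.
#'
#' @param spec a [model_spec()].
#' @param features numeric matrix or `feature_table`.
#' @param labels per-subject `"MCI"`/`"nMCI"`.
#' @param n_permutations number of label shuffles (the study convention is
#'   5000; calibration checks use far fewer).
#' @param seed integer seed for the shuffles.
#' @param selection_mode `"none"` (evaluate the given features as-is),
#'   `"per_permutation"` (re-run prune + penalized selection on the full
#'   data for the observed labels and for every permutation), or
#'   `"nested"` (additionally re-run selection inside every LOOCV training
#'   split).
#' @param inner_folds inner grid-search folds.
#' @param prune_threshold,lasso_folds selection-stage parameters.
#' @return list with `p`, `observed_auc`, `perm_auc` (vector),
#'   `n_permutations`.
#' @export
permutation_test <- function(spec, features, labels = NULL,
                             n_permutations = 5000L, seed = 1L,
                             selection_mode = c("none", "per_permutation",
                                                "nested"),
                             inner_folds = 5L, prune_threshold = 0.75,
                             lasso_folds = 10L) {
  selection_mode <- match.arg(selection_mode)
  if (n_permutations < 1L) stopf("`n_permutations` must be >= 1")
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$labels
    features <- features$matrix
  }
  x <- as.matrix(features)
  y <- as.character(labels)

  obs <- eval_auc_once(spec, x, y, selection_mode, inner_folds,
                       prune_threshold, lasso_folds,
                       lasso_seed = derive_seed(seed, 0L))
  perm_auc <- vapply(seq_len(n_permutations), function(b) {
    yp <- with_seed(derive_seed(seed, b), y[sample.int(length(y))])
    eval_auc_once(spec, x, yp, selection_mode, inner_folds,
                  prune_threshold, lasso_folds,
                  lasso_seed = derive_seed(seed, b))
  }, numeric(1))
  list(p = (1 + sum(perm_auc >= obs)) / (n_permutations + 1),
       observed_auc = obs, perm_auc = perm_auc,
       n_permutations = as.integer(n_permutations))
}

#' Evaluate one classifier end to end
#'
#' LOOCV predictions, metrics, feature weights from a full-data refit (with
#' hyperparameters chosen by the same inner grid search), and optionally a
#' permutation test.
#'
#' @inheritParams permutation_test
#' @param n_permutations 0 disables the permutation test.
#' @return a `model_report` including `feature_weights`,
#'   `chosen_hyperparameters` and, when requested, `permutation_p`.
#' @export
evaluate_model <- function(spec, features, labels = NULL,
                           n_permutations = 0L, seed = NULL,
                           inner_folds = 5L,
                           selection_mode = "none") {
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$labels
    features <- features$matrix
  }
  x <- as.matrix(features)
  y <- as.character(labels)
  seed <- seed %||% spec$seed

  held <- loocv_predict(spec, x, y, inner_folds = inner_folds)
  report <- compute_metrics(held$truth, held$pred, held$score)
  report$model <- spec$model

  hyper <- inner_grid_search(spec$model, x, y, spec$grid, k = inner_folds,
                             seed = derive_seed(seed, 424242L))
  std <- fit_standardizer(x)
  fit <- fit_one(spec$model, apply_standardizer(std, x), y, hyper,
                 seed = derive_seed(seed, 434343L))
  report$chosen_hyperparameters <- hyper
  report$feature_weights <- feature_weights(spec$model, fit, colnames(x))

  if (n_permutations > 0L) {
    pt <- permutation_test(spec, x, y, n_permutations = n_permutations,
                           seed = seed, selection_mode = selection_mode,
                           inner_folds = inner_folds)
    report$permutation_p <- pt$p
    report$n_permutations <- pt$n_permutations
  }
  report$held_out <- held
  report
}

#' Evaluate the three study classifiers under one protocol
#'
#' Linear SVM, random forest and logistic regression are run with identical
#' data, seeds and LOOCV protocol; the comparison table mirrors the usual
#' report layout (AUC, Accuracy, Sensitivity, Specificity, Kappa).
#'
#' @param features numeric matrix or `feature_table`.
#' @param labels per-subject `"MCI"`/`"nMCI"`.
#' @param seed master seed shared by all models.
#' @param grids optional named list of hyperparameter grids keyed by model.
#' @param n_permutations permutations per model (0 = none).
#' @param inner_folds inner grid-search folds.
#' @return list with `reports` (named list of `model_report`) and
#'   `comparison` (data.frame, one row per model).
#' @export
run_all_models <- function(features, labels = NULL, seed = 1L, grids = NULL,
                           n_permutations = 0L, inner_folds = 5L) {
  models <- c("svm_linear", "random_forest", "logistic_regression")
  reports <- lapply(models, function(m) {
    spec <- model_spec(m, grid = grids[[m]], seed = seed)
    evaluate_model(spec, features, labels, n_permutations = n_permutations,
                   seed = seed, inner_folds = inner_folds)
  })
  names(reports) <- models
  comparison <- data.frame(
    model = models,
    AUC = vapply(reports, `[[`, numeric(1), "auc"),
    Accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    Sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    Specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    Kappa = vapply(reports, `[[`, numeric(1), "kappa"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(reports = reports, comparison = comparison)
}

#' Write a model report as JSON
#' @param report a `model_report`.
#' @param path output path.
#' @export
write_model_report <- function(report, path) {
  stopifnot(inherits(report, "model_report"))
  jsonlite::write_json(list(
    model = report$model,
    confusion = as.list(report$confusion),
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, auc = report$auc,
    kappa = report$kappa, n = report$n,
    permutation_p = report$permutation_p,
    n_permutations = report$n_permutations,
    chosen_hyperparameters = report$chosen_hyperparameters,
    feature_weights = as.list(report$feature_weights)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
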