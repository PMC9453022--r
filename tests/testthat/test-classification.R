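test_that("pooled AUC equals the Mann-Whitney pair count, ties included", {
  set.seed(30)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    truth <- rep(c("MCI", "nMCI"), length.out = n)[sample.int(n)]
    score <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # many ties
    expect_equal(auc_pooled(score, truth), auc_pairwise_oracle(score, truth),
                 tolerance = 1e-12)
  }
})

test_that("pooled AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- rep(c("MCI", "nMCI"), c(12, 15))
  score <- rnorm(27)
  ours <- auc_pooled(score, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("nMCI", "MCI"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("AUC endpoints behave under perfect ranking and pure ties", {
  truth <- rep(c("MCI", "nMCI"), each = 5)
  expect_equal(auc_pooled(c(6:10, 1:5), truth), 1)
  expect_equal(auc_pooled(rep(0, 10), truth), 0.5)
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohen_kappa(10, 0, 0, 10), 1)
  # constant positive prediction on balanced truth: agreement is chance level
  expect_equal(cohen_kappa(10, 0, 10, 0), 0)
  expect_lt(abs(cohen_kappa(43, 8, 20, 28) - 0.429), 1e-3)
  expect_equal(cohen_kappa(c(43, 8, 20, 28)), cohen_kappa(43, 8, 20, 28))
})

test_that("metrics reconstruct the published-style confusion ratios", {
  v <- vectors_from_confusion(42, 9, 19, 29)
  set.seed(2)
  rep_ <- compute_metrics(v$truth, v$pred, score = rnorm(99))
  expect_equal(unname(rep_$confusion), c(42, 9, 19, 29))
  expect_lt(abs(rep_$sensitivity - 0.8235), 1e-4)
  expect_lt(abs(rep_$specificity - 0.6042), 1e-4)
  expect_lt(abs(rep_$accuracy - 0.7172), 1e-4)
  expect_error(compute_metrics(rep("MCI", 4), rep("MCI", 4), rnorm(4)),
               "both classes")
})

test_that("accuracy identity holds for every emitted report", {
  ft <- simulate_feature_table(n1 = 10, n2 = 8, seed = 40)
  out <- run_all_models(ft, seed = 3,
                        grids = list(svm_linear = list(C = 1),
                                     random_forest = list(n_trees = 100L,
                                                          max_depth = NA),
                                     logistic_regression = list(C = 1)))
  expect_equal(nrow(out$comparison), 3L)
  expect_identical(names(out$comparison)[-1],
                   c("AUC", "Accuracy", "Sensitivity", "Specificity", "Kappa"))
  for (r in out$reports) {
    npos <- r$confusion["TP"] + r$confusion["FN"]
    nneg <- r$confusion["TN"] + r$confusion["FP"]
    expect_equal(r$accuracy,
                 unname((r$sensitivity * npos + r$specificity * nneg) / r$n),
                 tolerance = 1e-12)
  }
})

test_that("LOOCV is perfect on well-separated clouds for all three models", {
  set.seed(50)
  n <- 16
  x <- rbind(matrix(rnorm(n / 2 * 2, mean = 5), n / 2, 2),
             matrix(rnorm(n / 2 * 2, mean = -5), n / 2, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c("MCI", "nMCI"), each = n / 2)
  for (m in c("svm_linear", "random_forest", "logistic_regression")) {
    held <- loocv_predict(model_spec(m, seed = 1), x, y)
    expect_equal(nrow(held), n)
    expect_identical(held$pred, y)
  }
})

test_that("null-data LOOCV accuracy is centered on chance", {
  # at study-scale n; small-n LOOCV carries a known pessimistic bias
  accs <- vapply(1:50, function(s) {
    ft <- null_features(100, 4, seed = 500 + s)
    held <- loocv_predict(model_spec("svm_linear", grid = list(C = 1),
                                     seed = s), ft)
    mean(held$pred == held$truth)
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("permutation p follows the add-one rule and is reproducible", {
  set.seed(60)
  x <- rbind(matrix(rnorm(12, mean = 4), 6, 2),
             matrix(rnorm(12, mean = -4), 6, 2))
  colnames(x) <- c("a", "b")
  y <- rep(c("MCI", "nMCI"), each = 6)
  spec <- model_spec("svm_linear", grid = list(C = 1), seed = 2)
  pt <- permutation_test(spec, x, y, n_permutations = 19, seed = 7)
  expect_equal(pt$observed_auc, 1)
  expect_equal(pt$p, 1 / 20)  # observed beats every permutation
  pt2 <- permutation_test(spec, x, y, n_permutations = 19, seed = 7)
  expect_identical(pt, pt2)
})

test_that("permutation p is valid under the null", {
  spec <- model_spec("svm_linear", grid = list(C = 1), seed = 1)
  ps <- vapply(1:200, function(s) {
    ft <- null_features(8, 2, seed = 9000 + s)
    permutation_test(spec, ft$matrix, ft$labels, n_permutations = 99,
                     seed = s)$p
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.05 + 0.03)
  expect_lte(mean(ps <= 0.10), 0.10 + 0.03)
})

test_that("feature weights identify drivers and normalize correctly", {
  set.seed(70)
  n <- 40
  x <- cbind(driver = rep(c(2, -2), each = n / 2) + rnorm(n, sd = 0.2),
             bland1 = rnorm(n), bland2 = rnorm(n))
  y <- rep(c("MCI", "nMCI"), each = n / 2)
  for (m in c("svm_linear", "logistic_regression")) {
    rep_ <- evaluate_model(model_spec(m, grid = list(C = 1), seed = 1), x, y)
    w <- rep_$feature_weights
    expect_equal(names(which.max(abs(w))), "driver")
    expect_gt(w["driver"], 0)  # oriented MCI-positive
  }
  repf <- evaluate_model(model_spec("random_forest",
                                    grid = list(n_trees = 200L,
                                                max_depth = NA), seed = 1),
                         x, y)
  wf <- repf$feature_weights
  expect_true(all(wf >= 0))
  expect_lt(abs(sum(wf) - 1), 1e-9)
})

test_that("duplicate features share the weight a single copy would carry", {
  set.seed(71)
  n <- 60
  f <- rep(c(1.5, -1.5), each = n / 2) + rnorm(n, sd = 0.5)
  y <- rep(c("MCI", "nMCI"), each = n / 2)
  x1 <- cbind(f = f, noise = rnorm(n))
  x2 <- cbind(f = f, f_twin = f, noise = x1[, "noise"])
  spec <- model_spec("logistic_regression", grid = list(C = 1), seed = 1)
  w1 <- evaluate_model(spec, x1, y)$feature_weights
  w2 <- evaluate_model(spec, x2, y)$feature_weights
  expect_equal(unname(w2["f"]), unname(w2["f_twin"]), tolerance = 1e-3)
  expect_lt(abs((abs(w2["f"]) + abs(w2["f_twin"])) - abs(w1["f"])) /
              abs(w1["f"]), 0.25)
})

test_that("requesting linear weights from a nonlinear kernel errors", {
  set.seed(72)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- label <- rep(c("MCI", "nMCI"), 10)
  fit <- e1071::svm(x, factor(y), kernel = "radial")
  expect_error(feature_weights("svm_linear", fit, c("a", "b")), "linear")
})

test_that("selection outside cross-validation inflates null AUC", {
  # screening selection applied once to all data (leaky) vs re-run inside
  # each LOOCV training split (nested): the leak shows as optimistic AUC
  screen_top3 <- function(x, y) {
    sc <- abs(apply(x, 2, function(col) cor(col, as.numeric(y == "MCI"))))
    names(sort(sc, decreasing = TRUE))[1:3]
  }
  spec <- model_spec("svm_linear", grid = list(C = 1), seed = 1)
  bias <- vapply(1:30, function(s) {
    ft <- null_features(20, 10, seed = 7000 + s)
    leaky_cols <- screen_top3(ft$matrix, ft$labels)
    leaky <- loocv_predict(spec, ft$matrix[, leaky_cols], ft$labels)
    nested <- loocv_predict(spec, ft$matrix, ft$labels,
                            select_fun = screen_top3)
    auc_pooled(leaky$score, leaky$truth) -
      auc_pooled(nested$score, nested$truth)
  }, numeric(1))
  expect_gt(mean(bias), 0)
})

test_that("strong synthetic separation yields high AUC for all models", {
  params <- data.frame(
    feature = c(sprintf("eff%d", 1:3), sprintf("null%d", 1:3)),
    mci_mean = c(2, 2, 2, 0, 0, 0), mci_sd = 1,
    nmci_mean = 0, nmci_sd = 1)
  ft <- simulate_feature_table(params, n1 = 25, n2 = 25, seed = 80)
  out <- run_all_models(ft, seed = 4,
                        grids = list(svm_linear = list(C = 1),
                                     random_forest = list(n_trees = 200L,
                                                          max_depth = NA),
                                     logistic_regression = list(C = 1)))
  expect_true(all(out$comparison$AUC >= 0.95))

  out2 <- run_all_models(ft, seed = 4,
                         grids = list(svm_linear = list(C = 1),
                                      random_forest = list(n_trees = 200L,
                                                           max_depth = NA),
                                      logistic_regression = list(C = 1)))
  expect_identical(out$comparison, out2$comparison)
})
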