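test_that("confusion-matrix metrics match a hand-computed example", {
  y_true <- c("low", "low", "medium", "medium", "high", "high")
  y_pred <- c("low", "medium", "medium", "medium", "high", "low")
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 4 / 6, tolerance = 1e-12)
  expect_equal(m$precision, mean(c(1 / 2, 2 / 3, 1)), tolerance = 1e-12)
  expect_equal(m$recall, mean(c(1 / 2, 1, 1 / 2)), tolerance = 1e-12)
  # macro F is the mean of per-class harmonic means
  f_by_hand <- mean(c(2 * (1/2 * 1/2) / (1/2 + 1/2),
                      2 * (2/3 * 1) / (2/3 + 1),
                      2 * (1 * 1/2) / (1 + 1/2)))
  expect_equal(m$f1, f_by_hand, tolerance = 1e-12)
  # accuracy equals trace(confusion) / total
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
  # per-class one-vs-rest counts are consistent with row sums
  for (cls in workload_levels()) {
    pc <- m$per_class[[cls]]
    expect_equal(pc$tp + pc$fn, sum(m$confusion[cls, ]))
    expect_equal(pc$tp + pc$tn + pc$fp + pc$fn, 6)
  }
})

test_that("metric edge cases: perfect, degenerate, mismatched", {
  y <- rep(workload_levels(), 4)
  m <- compute_metrics(y, y)
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1,
                 m$accuracy_ovr_macro), rep(1, 5))
  expect_warning(m2 <- compute_metrics(y, rep("low", 12)), "zero denominator")
  expect_equal(m2$accuracy, 1 / 3)
  expect_error(compute_metrics(y, y[-1]), "length mismatch")
  expect_error(compute_metrics(c("low", "extreme"), c("low", "low")),
               "alphabet")
})

test_that("rank-based AUC equals exhaustive concordant-pair counting", {
  brute_auc <- function(pos, s) {
    pairs <- expand.grid(i = which(pos), j = which(!pos))
    mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  }
  # 4-point toy set with one inversion
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  s <- c(0.9, 0.4, 0.6, 0.1)
  prob <- cbind(low = s, medium = 1 - s, high = 0)
  y <- ifelse(pos, "low", "medium")
  expect_warning(auc <- roc_auc_macro(y, prob[, 1, drop = FALSE]), NA)
  expect_equal(auc, brute_auc(pos, s))
  # random scores, larger set, including ties
  set.seed(3)
  pos2 <- rep(c(TRUE, FALSE), each = 25)
  s2 <- round(runif(50), 1)
  expect_equal(roc_auc_macro(ifelse(pos2, "high", "low"),
                             cbind(high = s2)),
               brute_auc(pos2, s2), tolerance = 1e-12)
})

test_that("AUC is 1 for perfect ranking and ~0.5 for label-free scores", {
  y <- rep(workload_levels(), each = 10)
  prob <- matrix(0.01, 30, 3, dimnames = list(NULL, workload_levels()))
  for (i in seq_along(y)) prob[i, y[i]] <- 0.98
  expect_equal(roc_auc_macro(y, prob), 1)
  set.seed(11)
  y2 <- sample(rep(workload_levels(), each = 200))
  prob2 <- matrix(runif(600 * 3), 600, 3,
                  dimnames = list(NULL, workload_levels()))
  expect_equal(roc_auc_macro(y2, prob2), 0.5, tolerance = 0.05)
  expect_warning(roc_auc_macro(rep("low", 5),
                               cbind(low = runif(5), medium = runif(5))),
                 "skipped")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  pos <- runif(40) > 0.5
  s <- rnorm(40) + pos
  ours <- roc_auc_macro(ifelse(pos, "high", "low"), cbind(high = s))
  ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(pos),
                                        predictor = s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("stacking separates well-separated classes and is deterministic", {
  d <- blob_data(n_per_class = 12, seed = 5)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  model <- fit_stacking(Z, d$y, seed = 2)
  p1 <- predict(model, Z)
  expect_gte(mean(p1$label == d$y), 0.95)
  expect_lt(max(abs(rowSums(p1$prob) - 1)), 1e-9)
  # same seed, same model, same predictions
  model2 <- fit_stacking(Z, d$y, seed = 2)
  p2 <- predict(model2, Z)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  # empty prediction input
  p0 <- predict(model, Z[0, , drop = FALSE])
  expect_length(p0$label, 0)
  # duplicate learner probabilities (collinear meta-features) still fit
  expect_error(fit_stacking(Z[1:3, ], factor(c("low", "low", "medium"),
                                             levels = workload_levels())),
               "at least 2")
  expect_error(predict(model, Z[, c(2, 1, 3, 4)]), "columns")
})

test_that("cross-validation partitions rows correctly and is seeded", {
  d <- blob_data(n_per_class = 20, seed = 6)
  rep1 <- cross_validate(d$X, d$y, k = 10,
                         selection = list(method = "none"), seed = 3)
  expect_length(rep1$folds, 60)
  expect_equal(sort(unique(rep1$folds)), 1:10)
  expect_true(all(table(rep1$folds) == 6))        # 10 disjoint folds of 6
  # stratification: every fold holds 2 of each class
  expect_true(all(table(rep1$folds, d$y) == 2))
  rep2 <- cross_validate(d$X, d$y, k = 10,
                         selection = list(method = "none"), seed = 3)
  expect_identical(rep1$folds, rep2$folds)
  expect_equal(rep1$mean, rep2$mean, tolerance = 1e-12)
  # separable blobs classify essentially perfectly
  expect_gte(rep1$mean$accuracy, 0.95)
  expect_true(jsonlite::validate(cv_report_json(rep1)))
})

test_that("grouped folds keep all of a subject's rows on one side", {
  d <- blob_data(n_per_class = 10, seed = 7)
  groups <- rep(sprintf("S%02d", 1:6), each = 5)
  # group folds can hold one-class test sets: metric warnings are expected
  rep1 <- suppressWarnings(
    cross_validate(d$X, d$y, k = 3, selection = list(method = "none"),
                   seed = 1, groups = groups)
  )
  for (g in unique(groups)) {
    expect_length(unique(rep1$folds[groups == g]), 1)
  }
})

test_that("non-stratifiable data falls back with a warning", {
  d <- blob_data(n_per_class = 4, seed = 8)
  # the fold-assignment fallback is the first warning raised
  w <- tryCatch(
    cross_validate(d$X, d$y, k = 6, selection = list(method = "none"),
                   seed = 1),
    warning = function(w) conditionMessage(w)
  )
  expect_match(w, "non-stratified")
})

test_that("grid search evaluates the full cross-product and picks the max", {
  d <- blob_data(n_per_class = 10, seed = 9)
  g1 <- grid_search(d$X, d$y, grids = list(svm_cost = 1), k = 5, seed = 1)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best_config$svm$cost, 1)
  g2 <- grid_search(d$X, d$y,
                    grids = list(svm_cost = c(0.01, 1), rf_ntree = 100),
                    k = 5, seed = 1)
  expect_equal(nrow(g2$table), 2)
  expect_equal(g2$best_row, which.max(g2$table$accuracy))
  expect_error(grid_search(d$X, d$y, grids = list()), "empty")
})
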