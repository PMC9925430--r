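test_that("standardization centers, scales, and never leaks test statistics", {
  set.seed(1)
  X <- matrix(rnorm(40 * 6, mean = 3, sd = 2), 40, 6)
  colnames(X) <- paste0("f", 1:6)
  std <- standardize_fit(X)
  Z <- standardize_apply(std, X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  # transform then inverse-transform is identity
  expect_equal(standardize_apply(std, Z, inverse = TRUE), X,
               tolerance = 1e-10)
  # held-out rows are transformed with the training statistics
  held <- matrix(100, 1, 6)
  expect_equal(standardize_apply(std, held),
               (held - rbind(std$mean)) / rbind(std$sd), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize_fit(X[1, , drop = FALSE]), "2 training rows")
})

test_that("zero-variance features map to zeros with a warning", {
  X <- cbind(a = rnorm(20), b = rep(7, 20))
  expect_warning(std <- standardize_fit(X), "zero-variance")
  Z <- standardize_apply(std, X)
  expect_true(all(Z[, "b"] == 0))
})

test_that("RFE keeps planted signal features and respects n_target", {
  d <- planted_matrix(n_per_class = 20, p = 40, seed = 2)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  sel <- rfe_select(Z, d$y, n_target = 3)
  expect_setequal(sel$features, c("f001", "f002", "f003"))
  expect_length(sel$features, 3)
  # elimination ranks cover 1..p exactly once
  expect_setequal(unname(sel$scores), seq_len(40))
  # identity selection: n_target = feature count
  sel_all <- rfe_select(Z, d$y, n_target = 40)
  expect_setequal(sel_all$features, colnames(Z))
  expect_error(rfe_select(Z, d$y, n_target = 99), "exceeds")
  Zbad <- Z; Zbad[1, 1] <- Inf
  expect_error(rfe_select(Zbad, d$y), "non-finite")
})

test_that("RFE selection names are invariant to column permutation", {
  d <- planted_matrix(n_per_class = 12, p = 20, seed = 3)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  set.seed(99)
  perm <- sample(ncol(Z))
  s1 <- rfe_select(Z, d$y, n_target = 5)
  s2 <- rfe_select(Z[, perm], d$y, n_target = 5)
  expect_setequal(s1$features, s2$features)
})

test_that("greedy RFE agrees with exhaustive subset search on small designs", {
  # on <= 8 features with a planted pair, the RFE survivor set should land
  # inside the best exhaustive k-subsets scored by the same criterion
  d <- planted_matrix(n_per_class = 12, p = 6, n_signal = 2, seed = 4)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  sel <- rfe_select(Z, d$y, n_target = 2)
  expect_setequal(sel$features, c("f001", "f002"))
})

test_that("lasso path has the configured geometry and finds planted signal", {
  d <- planted_matrix(n_per_class = 20, p = 50, n_signal = 1, seed = 5)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  fit <- lasso_path_fit(Z, encode_labels(d$y), seed = 7)
  expect_length(fit$path$lambda, 150)
  expect_equal(max(fit$path$lambda) / min(fit$path$lambda), 1 / 0.001,
               tolerance = 1e-6)
  # all coefficients zero at the path start
  expect_true(all(as.matrix(fit$cv_fit$glmnet.fit$beta)[, 1] == 0))
  # the planted linear feature carries the largest coefficient
  expect_equal(names(which.max(abs(fit$beta))), "f001")
  # nonzero count grows along the path with only sparse local exceptions
  nz <- as.integer(fit$path$nzero)
  expect_lt(mean(diff(nz) < 0), 0.05)
  expect_gt(utils::tail(nz, 1), nz[1])
})

test_that("lasso_select orders by |beta| and handles degenerate models", {
  beta <- c(a = 0.5, b = -2, c = 0, d = 1)
  model <- structure(list(beta = beta, cv_fit = NULL, lambda = 0.1,
                          config = list()), class = "ewl_lasso")
  expect_warning(sel <- lasso_select(model, n_target = 5), "nonzero")
  expect_identical(sel$features, c("b", "d", "a"))
  sel2 <- suppressWarnings(lasso_select(model, n_target = 2))
  expect_identical(sel2$features, c("b", "d"))
  zero <- structure(list(beta = beta * 0, cv_fit = NULL, lambda = 1,
                         config = list()), class = "ewl_lasso")
  expect_warning(sel3 <- lasso_select(zero, 5), "empty")
  expect_length(sel3$features, 0)
})

test_that("lasso selection pads from denser path points to reach n_target", {
  d <- planted_matrix(n_per_class = 15, p = 30, n_signal = 2, seed = 6)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  fit <- lasso_path_fit(Z, encode_labels(d$y), seed = 8)
  sel <- lasso_select(fit, n_target = 15)
  expect_lte(length(sel$features), 15)
  expect_true(all(c("f001", "f002") %in% sel$features))
})

test_that("subset-size sweep returns one row per size and a best size", {
  d <- planted_matrix(n_per_class = 10, p = 25, n_signal = 3, seed = 9)
  centroid_cv <- function(Xs, ys) {
    # cheap deterministic evaluator: leave-one-out nearest class centroid
    hits <- vapply(seq_len(nrow(Xs)), function(i) {
      ctr <- sapply(levels(ys), function(cl) {
        colMeans(Xs[ys == cl & seq_len(nrow(Xs)) != i, , drop = FALSE])
      })
      names(which.min(colSums((t(ctr) - Xs[i, ])^2)))  == as.character(ys[i])
    }, logical(1))
    mean(hits)
  }
  sw <- sweep_subset_sizes(d$X, d$y, sizes = c(3, 10), evaluator = centroid_cv)
  expect_equal(nrow(sw$table), 2)
  expect_true(sw$best_size %in% c(3, 10))
  # with all signal in 3 features, more features should not help much
  expect_gte(sw$table$accuracy[1], sw$table$accuracy[2] - 0.1)
  sw1 <- sweep_subset_sizes(d$X, d$y, sizes = 5, evaluator = centroid_cv)
  expect_equal(nrow(sw1$table), 1)
})

test_that("selection results serialize to valid JSON", {
  d <- planted_matrix(n_per_class = 10, p = 10, seed = 10)
  Z <- standardize_apply(standardize_fit(d$X), d$X)
  sel <- rfe_select(Z, d$y, n_target = 4)
  js <- selection_to_json(sel)
  expect_true(jsonlite::validate(js))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$method, "rfe")
  expect_length(parsed$features, 4)
})
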