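# Feature selection: standardization, SVM recursive feature elimination,
# and cross-validated lasso on the ordinal-encoded workload label.

#' Fit standardization parameters on training rows
#'
#' Per-feature mean and standard deviation estimated on the training rows
#' only; applying them to held-out rows uses these training statistics, never
#' the held-out rows' own (the anti-leakage contract). Zero-variance columns
#' are mapped to all-zeros with a warning.
#'
#' @param X Numeric training matrix (rows = segments).
#' @return An `ewl_standardizer` with `mean`, `sd` and `zero_var` flags.
#' @export
standardize_fit <- function(X) {
  if (nrow(X) < 2) stop("need at least 2 training rows to standardize")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  zero <- sd <= .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) mapped to zeros")
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd, zero_var = zero),
            class = "ewl_standardizer")
}

#' Apply (or invert) fitted standardization
#'
#' @param params An `ewl_standardizer` from [standardize_fit()].
#' @param X Rows to transform (columns must match the training columns).
#' @param inverse Undo the transform instead.
#' @return Transformed matrix.
#' @export
standardize_apply <- function(params, X, inverse = FALSE) {
  if (ncol(X) != length(params$mean)) stop("column count mismatch")
  if (inverse) {
    out <- sweep(sweep(X, 2, params$sd, "*"), 2, params$mean, "+")
  } else {
    out <- sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
    out[, params$zero_var] <- 0
  }
  out
}

# Linear SVM squared-weight score per feature: the RFE ranking criterion.
# One binary SVM per class pair (the decomposition a multiclass linear SVC
# actually fits), scores summed over the pairwise weight vectors. Pairwise
# problems stay linearly separable when the class effect is ordered, which a
# middle-class-vs-rest split is not.
svm_feature_scores <- function(X, y, cost = 1) {
  scores <- numeric(ncol(X))
  cls <- levels(y)
  for (i in seq_len(length(cls) - 1)) {
    for (j in seq(i + 1, length(cls))) {
      sel <- y %in% cls[c(i, j)]
      fit <- e1071::svm(X[sel, , drop = FALSE], droplevels(y[sel]),
                        kernel = "linear", cost = cost, scale = FALSE)
      w <- crossprod(fit$coefs, fit$SV)
      scores <- scores + as.numeric(w)^2
    }
  }
  scores
}

#' Recursive feature elimination with a linear SVM
#'
#' Iteratively fits pairwise linear SVMs (C = 1 by default, one per class
#' pair, as a multiclass linear SVC does), scores each surviving feature by
#' the sum over the pairwise weight vectors of squared weights, removes the
#' `step` lowest-scoring features, and repeats until `n_target` remain.
#' Score ties are broken by canonical column order: the earlier column
#' survives.
#'
#' @param X Numeric matrix (standardized features).
#' @param y Factor of class labels (>= 2 classes).
#' @param n_target Number of features to keep (15 by default, the subset
#'   size that maximized downstream accuracy in the subset-size sweep).
#' @param step Features removed per iteration.
#' @param cost SVM regularization constant C.
#' @return An `ewl_selection`: `method`, `features` (survivors ordered by
#'   final score, strongest first), `scores` (elimination rank per original
#'   feature: 1 = eliminated first, larger = survived longer), and the
#'   configuration.
#' @export
rfe_select <- function(X, y, n_target = 15, step = 1, cost = 1) {
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (n_target > ncol(X)) stop("n_target exceeds feature count")
  surviving <- seq_len(ncol(X))
  rank_out <- integer(ncol(X))
  n_removed <- 0L
  scores <- svm_feature_scores(X[, surviving, drop = FALSE], y, cost)
  while (length(surviving) > n_target) {
    k <- min(step, length(surviving) - n_target)
    # weakest first; among score ties the later column goes first
    ord <- order(scores, -surviving)
    drop_pos <- ord[seq_len(k)]
    rank_out[surviving[drop_pos]] <- n_removed + seq_len(k)
    n_removed <- n_removed + k
    surviving <- surviving[-drop_pos]
    scores <- svm_feature_scores(X[, surviving, drop = FALSE], y, cost)
  }
  rank_out[surviving] <- n_removed + rank(scores, ties.method = "first")
  sel_order <- surviving[order(scores, decreasing = TRUE)]
  structure(
    list(method = "rfe",
         features = colnames(X)[sel_order],
         scores = stats::setNames(rank_out, colnames(X)),
         final_scores = stats::setNames(scores[order(scores,
                                                     decreasing = TRUE)],
                                        colnames(X)[sel_order]),
         config = list(n_target = n_target, step = step, cost = cost)),
    class = "ewl_selection"
  )
}

#' Ordinal encoding of workload labels
#'
#' Workload is an ordered construct, so the regression-type lasso target
#' encodes low = 0, medium = 1, high = 2.
#'
#' @param y Factor or character vector of workload labels.
#' @return Numeric vector in `{0, 1, 2}`.
#' @export
encode_labels <- function(y) {
  match(as.character(y), workload_levels()) - 1
}

#' Cross-validated lasso along a regularization path
#'
#' Squared-error lasso solved along a geometric grid of 150 lambda values
#' spanning `[eps * lambda_max, lambda_max]` (lambda_max = smallest lambda
#' with an all-zero solution), with the best lambda chosen by k-fold
#' cross-validated mean squared error. Fitted with glmnet coordinate
#' descent; non-convergence within `max_iter` surfaces as a glmnet warning.
#'
#' @param X Standardized numeric matrix.
#' @param y_encoded Numeric target (see [encode_labels()]).
#' @param n_alphas Path length (number of lambda values).
#' @param eps Path length ratio `lambda_min / lambda_max`.
#' @param max_iter Maximum coordinate-descent iterations.
#' @param tol Convergence threshold.
#' @param k CV folds.
#' @param seed Seed for the CV fold assignment.
#' @return An `ewl_lasso`: coefficients `beta` and `intercept` at the
#'   CV-best lambda, `lambda`, the full `path` (lambda grid, nonzero counts,
#'   CV error) and the underlying cv.glmnet fit.
#' @export
lasso_path_fit <- function(X, y_encoded, n_alphas = 150, eps = 0.001,
                           max_iter = 1500, tol = 1e-4, k = 10, seed = 1) {
  stopifnot(is.numeric(y_encoded))
  set.seed(seed)
  # explicit geometric grid so the path always holds n_alphas values
  # (glmnet's automatic path stops early once the deviance saturates)
  lambda_max <- max(abs(crossprod(X, y_encoded - mean(y_encoded)))) /
    length(y_encoded)
  grid <- exp(seq(log(lambda_max), log(eps * lambda_max),
                  length.out = n_alphas))
  cv <- glmnet::cv.glmnet(X, y_encoded, family = "gaussian", lambda = grid,
                          maxit = max_iter, thresh = tol, nfolds = k,
                          standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  names(beta) <- colnames(X)
  structure(
    list(beta = beta,
         intercept = as.numeric(stats::coef(cv, s = "lambda.min"))[1],
         lambda = cv$lambda.min,
         path = list(lambda = cv$lambda, nzero = cv$nzero, cvm = cv$cvm),
         cv_fit = cv,
         config = list(n_alphas = n_alphas, eps = eps, max_iter = max_iter,
                       tol = tol, k = k)),
    class = "ewl_lasso"
  )
}

#' Select features from a fitted lasso model
#'
#' Features with nonzero coefficients at the CV-best lambda, ordered by
#' absolute coefficient descending (ties broken by canonical column order).
#' When more than `n_target` are nonzero the list is truncated; when fewer,
#' it is padded from the next-densest points along the path; if the whole
#' path never reaches `n_target` nonzero coefficients, all nonzero features
#' are returned with a warning.
#'
#' @param model An `ewl_lasso` from [lasso_path_fit()].
#' @param n_target Target number of features.
#' @return An `ewl_selection` with per-feature scores `|beta|`.
#' @export
lasso_select <- function(model, n_target = 15) {
  ab <- abs(model$beta)
  nz <- which(ab > 0)
  ord <- nz[order(ab[nz], nz, decreasing = c(TRUE, FALSE), method = "radix")]
  selected <- names(model$beta)[ord]
  scores <- ab[ord]

  if (length(selected) < n_target && !is.null(model$cv_fit)) {
    full_beta <- as.matrix(model$cv_fit$glmnet.fit$beta)
    dens_order <- order(model$path$lambda)  # denser fits at smaller lambda
    for (j in dens_order) {
      if (length(selected) >= n_target) break
      bj <- abs(full_beta[, j])
      cand <- setdiff(names(bj)[bj > 0][order(-bj[bj > 0])], selected)
      add <- utils::head(cand, n_target - length(selected))
      selected <- c(selected, add)
      scores <- c(scores, bj[add])
    }
  }
  if (length(selected) == 0) warning("all-zero lasso model: empty selection")
  else if (length(selected) < n_target) {
    warning("only ", length(selected), " nonzero features on the path; ",
            "returning all of them")
  }
  structure(
    list(method = "lasso_cv",
         features = utils::head(selected, n_target),
         scores = stats::setNames(utils::head(scores, n_target),
                                  utils::head(selected, n_target)),
         config = c(model$config, list(n_target = n_target,
                                       lambda = model$lambda))),
    class = "ewl_selection"
  )
}

#' One-call selection front-end
#'
#' @param X Standardized matrix; `y` factor labels.
#' @param y Class labels.
#' @param method `"rfe"` or `"lasso"`.
#' @param n_target Number of features to keep.
#' @param seed Seed (lasso CV folds).
#' @param ... Passed to the underlying selector.
#' @return An `ewl_selection`.
#' @export
select_features <- function(X, y, method = c("rfe", "lasso"), n_target = 15,
                            seed = 1, ...) {
  method <- match.arg(method)
  if (method == "rfe") {
    rfe_select(X, y, n_target = n_target, ...)
  } else {
    lasso_select(lasso_path_fit(X, encode_labels(y), seed = seed, ...),
                 n_target = n_target)
  }
}

#' Sweep candidate subset sizes
#'
#' For each candidate size, select that many features and evaluate them with
#' the supplied downstream evaluator (by default the stacking ensemble's
#' cross-validated mean macro accuracy). Returns the full size-to-accuracy
#' table and the argmax size.
#'
#' @param X Feature matrix; `y` labels.
#' @param y Class labels.
#' @param sizes Candidate subset sizes.
#' @param method Selection method, `"rfe"` or `"lasso"`.
#' @param evaluator `function(X_selected, y) -> accuracy`; default runs
#'   [cross_validate()] with the default stacking configuration and no inner
#'   selection.
#' @param seed Seed.
#' @param ... Passed to [cross_validate()] by the default evaluator.
#' @return List with `table` (data.frame size, accuracy) and `best_size`.
#' @export
sweep_subset_sizes <- function(X, y, sizes = c(5, 10, 15, 20, 30, 40),
                               method = "rfe", evaluator = NULL, seed = 1,
                               ...) {
  if (is.null(evaluator)) {
    evaluator <- function(Xs, ys) {
      rep <- cross_validate(Xs, ys, selection = list(method = "none"),
                            seed = seed, ...)
      rep$mean$accuracy
    }
  }
  std <- standardize_fit(X)
  Xs <- standardize_apply(std, X)
  acc <- vapply(sizes, function(sz) {
    sel <- select_features(Xs, y, method = method, n_target = sz, seed = seed)
    evaluator(X[, sel$features, drop = FALSE], y)
  }, numeric(1))
  tab <- data.frame(size = sizes, accuracy = acc)
  list(table = tab, best_size = sizes[which.max(acc)])
}

#' Serialize a selection result to JSON
#'
#' @param sel An `ewl_selection`.
#' @return JSON string (method, ordered names, scores, config snapshot).
#' @export
selection_to_json <- function(sel) {
  jsonlite::toJSON(
    list(method = sel$method, features = sel$features,
         scores = as.list(sel$scores), config = sel$config),
    auto_unbox = TRUE, digits = NA
  )
}
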