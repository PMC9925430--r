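# Two-level stacking ensemble (SVM + random forest + logistic regression,
# random-forest meta-learner), macro-averaged metrics, rank-based ROC-AUC,
# stratified k-fold cross-validation and exhaustive grid search.

#' Stacking ensemble configuration
#'
#' Level-1 learners: RBF-kernel SVM (C = 1, gamma = 0.01), random forest
#' (500 trees), multinomial logistic regression (L2 weight decay,
#' convergence tolerance 1e-4). Level-2 meta-learner: a random forest with
#' the same hyperparameters as the level-1 forest. Meta-features for
#' training the meta-learner are out-of-fold class-probability vectors from
#' an internal k-fold over the training rows.
#'
#' @param svm_cost,svm_gamma SVM hyperparameters.
#' @param rf_ntree Trees per random forest.
#' @param lr_decay,lr_tol L2 weight decay and convergence tolerance of the
#'   multinomial logistic fit.
#' @param internal_folds Folds used to generate out-of-fold meta-features.
#' @return An `ewl_stacking_config` list.
#' @export
stacking_config <- function(svm_cost = 1, svm_gamma = 0.01, rf_ntree = 500,
                            lr_decay = 1e-4, lr_tol = 1e-4,
                            internal_folds = 5) {
  stopifnot(internal_folds >= 2)
  structure(
    list(svm = list(cost = svm_cost, gamma = svm_gamma),
         rf = list(ntree = rf_ntree),
         lr = list(decay = lr_decay, tol = lr_tol),
         internal_folds = internal_folds),
    class = "ewl_stacking_config"
  )
}

# --- level-1 learners: fit and class-probability prediction ----------------

# Feature names may contain ":" (illegal in model formulas), so the logistic
# fit sees positional column names.
positional_df <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  df
}

fit_level1 <- function(X, y, cfg) {
  rownames(X) <- NULL  # duplicated rownames confuse downstream predictors
  df <- positional_df(X)
  list(
    svm = e1071::svm(X, y, kernel = "radial", cost = cfg$svm$cost,
                     gamma = cfg$svm$gamma, probability = TRUE,
                     scale = FALSE),
    rf = randomForest::randomForest(X, y, ntree = cfg$rf$ntree),
    lr = nnet::multinom(y ~ ., data = cbind(df, y = y), trace = FALSE,
                        decay = cfg$lr$decay, reltol = cfg$lr$tol,
                        maxit = 500, MaxNWts = 5000)
  )
}

predict_level1_probs <- function(models, X, levels) {
  rownames(X) <- NULL
  if (nrow(X) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 3 * length(levels)))
  }
  df <- positional_df(X)
  # align a learner's probability matrix onto the full class alphabet
  # (a learner trained on a subset of classes reports 0 for the rest)
  align <- function(p) {
    out <- matrix(0, nrow(X), length(levels), dimnames = list(NULL, levels))
    keep <- intersect(colnames(p), levels)
    out[, keep] <- p[, keep, drop = FALSE]
    out
  }
  p_svm <- attr(stats::predict(models$svm, X, probability = TRUE),
                "probabilities")
  p_rf <- stats::predict(models$rf, X, type = "prob")
  lr_lev <- models$lr$lev
  p_lr <- stats::predict(models$lr, newdata = df, type = "probs")
  if (is.null(dim(p_lr))) {
    if (length(lr_lev) == 2) {
      # binary multinom reports only P(second level)
      p_lr <- cbind(1 - p_lr, p_lr)
      colnames(p_lr) <- lr_lev
    } else {
      p_lr <- matrix(p_lr, nrow = 1, dimnames = list(NULL, lr_lev))
    }
  }
  cbind(align(p_svm), align(p_rf), align(p_lr))
}

#' Fit the two-level stacking ensemble
#'
#' Out-of-fold class-probability vectors from an internal stratified k-fold
#' over the training rows form the meta-feature matrix (3 probabilities per
#' learner, 9 columns); a random forest is trained on them as the
#' meta-learner; the level-1 learners are then refit on all training rows
#' for prediction time.
#'
#' @param X Standardized training matrix.
#' @param y Factor labels (all classes must be present, >= 2 rows each).
#' @param cfg An `ewl_stacking_config`.
#' @param seed Integer; fixes internal fold assignment and forest
#'   randomness, so identical seeds give identical predictions.
#' @return An `ewl_stacking` fitted model.
#' @export
fit_stacking <- function(X, y, cfg = stacking_config(), seed = 1) {
  y <- as.factor(y)
  if (all(levels(y) %in% workload_levels())) {
    y <- factor(y, levels = intersect(workload_levels(), levels(y)))
  }
  if (any(table(y) < 2)) {
    stop("every class needs at least 2 training rows; got: ",
         paste(names(table(y)), table(y), collapse = ", "))
  }
  set.seed(seed)
  lev <- levels(y)
  folds <- stratified_folds(y, cfg$internal_folds)
  meta <- matrix(NA_real_, nrow = nrow(X), ncol = 3 * length(lev))
  for (f in seq_len(cfg$internal_folds)) {
    tr <- folds != f
    if (all(tr)) next  # empty internal fold on very small training sets
    models <- fit_level1(X[tr, , drop = FALSE], droplevels(y[tr]), cfg)
    meta[!tr, ] <- predict_level1_probs(models, X[!tr, , drop = FALSE], lev)
  }
  colnames(meta) <- paste0(rep(c("svm", "rf", "lr"), each = length(lev)),
                           ".", rep(lev, 3))
  meta_rf <- randomForest::randomForest(meta, y, ntree = cfg$rf$ntree)
  level1 <- fit_level1(X, y, cfg)
  structure(
    list(level1 = level1, meta_model = meta_rf, levels = lev, cfg = cfg,
         columns = colnames(X), meta_columns = colnames(meta)),
    class = "ewl_stacking"
  )
}

#' Predict workload classes and probabilities from a stacking model
#'
#' @param object An `ewl_stacking` model.
#' @param newdata Matrix with the training columns.
#' @param ... Unused.
#' @return List with `label` (factor; argmax probability, ties to the
#'   lexicographically first class label) and `prob` (rows sum to 1).
#' @export
predict.ewl_stacking <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) {
    return(list(label = factor(character(0), levels = object$levels),
                prob = matrix(numeric(0), ncol = length(object$levels),
                              dimnames = list(NULL, object$levels))))
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$columns)) {
    stop("prediction columns do not match training columns")
  }
  meta <- predict_level1_probs(object$level1, newdata, object$levels)
  colnames(meta) <- object$meta_columns
  prob <- stats::predict(object$meta_model, meta, type = "prob")
  prob <- prob[, object$levels, drop = FALSE]
  prob <- prob / rowSums(prob)
  lab <- apply(prob, 1, function(p) {
    top <- which(p == max(p))
    object$levels[top][order(object$levels[top])][1]
  })
  list(label = factor(lab, levels = object$levels), prob = prob)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# to folds round-robin. Uses the current RNG state.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Confusion matrix and macro-averaged metrics
#'
#' Builds the 3x3 (true x predicted) confusion matrix, derives per-class
#' one-vs-rest TP/TN/FP/FN, and macro-averages precision, recall and
#' F-score (harmonic mean per class before averaging). A per-class metric
#' with a zero denominator is defined as 0 with a warning. Plain multiclass
#' accuracy (trace over total) is the primary accuracy; the one-vs-rest
#' macro accuracy is also reported.
#'
#' @param y_true,y_pred Equal-length label vectors from the workload
#'   alphabet.
#' @return An `ewl_metrics` list: `confusion`, `accuracy`,
#'   `accuracy_ovr_macro`, `precision`, `recall`, `f1` (macro), `per_class`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- workload_levels()
  y_true <- factor(as.character(y_true), levels = lev)
  y_pred <- factor(as.character(y_pred), levels = lev)
  if (anyNA(y_true) || anyNA(y_pred)) stop("labels outside the alphabet")
  cm <- table(true = y_true, predicted = y_pred)
  n <- sum(cm)
  per_class <- lapply(lev, function(cls) {
    tp <- cm[cls, cls]
    fp <- sum(cm[, cls]) - tp
    fn <- sum(cm[cls, ]) - tp
    tn <- n - tp - fp - fn
    safe <- function(num, den, what) {
      if (den == 0) {
        warning("zero denominator for ", what, " of class ", cls,
                "; defined as 0")
        return(0)
      }
      num / den
    }
    prec <- safe(tp, tp + fp, "precision")
    rec <- safe(tp, tp + fn, "recall")
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    list(tp = tp, tn = tn, fp = fp, fn = fn, precision = prec,
         recall = rec, f1 = f1, accuracy_ovr = (tp + tn) / n)
  })
  names(per_class) <- lev
  structure(
    list(confusion = cm,
         accuracy = sum(diag(cm)) / n,
         accuracy_ovr_macro = mean(vapply(per_class, `[[`, 1, "accuracy_ovr")),
         precision = mean(vapply(per_class, `[[`, 1, "precision")),
         recall = mean(vapply(per_class, `[[`, 1, "recall")),
         f1 = mean(vapply(per_class, `[[`, 1, "f1")),
         per_class = per_class),
    class = "ewl_metrics"
  )
}

# Binary AUC by the rank statistic with midranks for ties; equivalent to
# trapezoidal integration of the ROC curve.
auc_rank <- function(positive, scores) {
  r <- rank(scores)
  npos <- sum(positive)
  nneg <- sum(!positive)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Macro-averaged one-vs-rest ROC-AUC
#'
#' Per-class AUC computed from the class-probability column by the rank
#' statistic (midranks for ties), unweighted mean over classes. A class
#' absent from `y_true` is skipped with a warning.
#'
#' @param y_true Label vector.
#' @param prob Matrix of class probabilities with class-named columns.
#' @return Scalar macro AUC.
#' @export
roc_auc_macro <- function(y_true, prob) {
  y_true <- as.character(y_true)
  aucs <- c()
  for (cls in colnames(prob)) {
    pos <- y_true == cls
    if (!any(pos) || all(pos)) {
      warning("class ", cls, " absent from one side of y_true; skipped")
      next
    }
    aucs <- c(aucs, auc_rank(pos, prob[, cls]))
  }
  if (length(aucs) == 0) return(NA_real_)
  mean(aucs)
}

#' Stratified k-fold cross-validation of the full analysis chain
#'
#' Within each fold: fit the standardizer on the training rows, optionally
#' run feature selection on the (standardized) training rows only, fit the
#' stacking ensemble, and evaluate on the held-out fold. Nothing from a test
#' fold ever reaches its training pipeline. Fold assignment is seeded and
#' recorded in the report.
#'
#' @param X Numeric feature matrix (unstandardized); named columns.
#' @param y Factor or character workload labels.
#' @param k Number of folds (10 by default).
#' @param cfg An `ewl_stacking_config`.
#' @param selection List: `method` (`"rfe"`, `"lasso"` or `"none"`),
#'   `n_target`, and `mode` — `"fold"` (selection inside each training fold,
#'   the default, leak-free) or `"global"` (selection once on all rows
#'   before the folds, for strict replication of a selection-outside-CV
#'   workflow).
#' @param seed Integer seed for fold assignment and learner randomness.
#' @param groups Optional grouping vector (e.g. subject ids): folds then
#'   split groups, not rows, so no subject appears in both sides of a fold.
#' @return An `ewl_cv_report`: per-fold metrics and confusion matrices,
#'   aggregate mean and SD of each macro metric, fold assignment, selected
#'   features per fold, config snapshot and seed.
#' @export
cross_validate <- function(X, y, k = 10,
                           cfg = stacking_config(),
                           selection = list(method = "rfe", n_target = 15,
                                            mode = "fold"),
                           seed = 1, groups = NULL) {
  y <- factor(as.character(y), levels = workload_levels())
  if (nrow(X) < k) stop("fewer rows than folds")
  selection$method <- selection$method %||% "none"
  selection$mode <- selection$mode %||% "fold"
  selection$n_target <- selection$n_target %||% 15
  set.seed(seed)

  if (!is.null(groups)) {
    g <- factor(groups)
    gfold <- rep_len(seq_len(k), nlevels(g))[sample.int(nlevels(g))]
    folds <- gfold[as.integer(g)]
  } else if (min(table(y)) < k) {
    warning("a class has fewer than k members; non-stratified folds used")
    folds <- rep_len(seq_len(k), length(y))[sample.int(length(y))]
  } else {
    folds <- stratified_folds(y, k)
  }

  global_sel <- NULL
  if (selection$method != "none" && selection$mode == "global") {
    std_all <- standardize_fit(X)
    global_sel <- select_features(standardize_apply(std_all, X), y,
                                  method = selection$method,
                                  n_target = selection$n_target, seed = seed)
  }

  fold_metrics <- list()
  fold_sel <- list()
  for (f in seq_len(k)) {
    tr <- folds != f
    stopifnot(sum(!tr) > 0, !any(which(tr) %in% which(!tr)))
    std <- standardize_fit(X[tr, , drop = FALSE])
    Xtr <- standardize_apply(std, X[tr, , drop = FALSE])
    Xte <- standardize_apply(std, X[!tr, , drop = FALSE])
    feats <- colnames(X)
    if (!is.null(global_sel)) {
      feats <- global_sel$features
    } else if (selection$method != "none") {
      sel <- select_features(Xtr, droplevels(y[tr]),
                             method = selection$method,
                             n_target = selection$n_target, seed = seed)
      feats <- sel$features
    }
    fold_sel[[f]] <- feats
    model <- fit_stacking(Xtr[, feats, drop = FALSE], droplevels(y[tr]),
                          cfg, seed = seed + f)
    pred <- stats::predict(model, Xte[, feats, drop = FALSE])
    m <- compute_metrics(y[!tr], pred$label)
    m$auc <- roc_auc_macro(y[!tr], pred$prob)
    fold_metrics[[f]] <- m
  }

  agg <- function(field) {
    v <- vapply(fold_metrics, `[[`, numeric(1), field)
    c(mean = mean(v), sd = stats::sd(v))
  }
  fields <- c("accuracy", "accuracy_ovr_macro", "precision", "recall",
              "f1", "auc")
  summary <- vapply(fields, agg, numeric(2))
  structure(
    list(fold_metrics = fold_metrics,
         folds = folds,
         selected = fold_sel,
         mean = as.list(summary["mean", ]),
         sd = as.list(summary["sd", ]),
         k = k, seed = seed, selection = selection, cfg = cfg),
    class = "ewl_cv_report"
  )
}

#' Serialize a CV report to JSON
#'
#' @param report An `ewl_cv_report`.
#' @return JSON string.
#' @export
cv_report_json <- function(report) {
  per_fold <- lapply(report$fold_metrics, function(m) {
    list(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
         f1 = m$f1, auc = m$auc,
         confusion = as.data.frame.matrix(unclass(m$confusion)))
  })
  jsonlite::toJSON(
    list(mean = report$mean, sd = report$sd, per_fold = per_fold,
         folds = report$folds, k = report$k, seed = report$seed,
         selection = report$selection,
         config = unclass(report$cfg)),
    auto_unbox = TRUE, digits = NA
  )
}

#' Exhaustive grid search over stacking hyperparameters
#'
#' Evaluates every point of the grids' cross-product by k-fold mean macro
#' accuracy; ties go to the first grid point in iteration order.
#'
#' @param X,y Data as in [cross_validate()].
#' @param grids Named list of candidate value vectors; names address
#'   [stacking_config()] arguments (e.g. `svm_cost`, `svm_gamma`,
#'   `rf_ntree`).
#' @param k Folds.
#' @param seed Seed.
#' @param selection Selection settings as in [cross_validate()].
#' @return List with `best_config` (an `ewl_stacking_config`), `best_row`,
#'   and `table` (one row per grid point with its mean accuracy).
#' @export
grid_search <- function(X, y, grids, k = 10, seed = 1,
                        selection = list(method = "none")) {
  if (length(grids) == 0) stop("empty grid")
  tab <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  acc <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- do.call(stacking_config, as.list(tab[i, , drop = FALSE]))
    rep_i <- cross_validate(X, y, k = k, cfg = cfg, selection = selection,
                            seed = seed)
    acc[i] <- rep_i$mean$accuracy
  }
  tab$accuracy <- acc
  best <- which.max(acc)  # first maximum wins ties
  list(best_config = do.call(stacking_config,
                             as.list(tab[best, setdiff(names(tab), "accuracy"),
                                         drop = FALSE])),
       best_row = best, table = tab)
}
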