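#' Area under the ROC curve (rank statistic)
#'
#' Equals the probability that a random positive outscores a random negative
#' (ties counted half), i.e. the normalized Mann-Whitney U statistic — and
#' therefore the concordant-pair fraction.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @return auROC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- labels == sort(unique(labels))[2]
  as.integer(as.logical(labels))
}

#' Confusion-matrix metrics at a threshold
#'
#' @param predicted Binary predictions (0/1 or logical).
#' @param labels True binary labels.
#' @return Named list: sensitivity, specificity, precision, f1, accuracy.
#'   Undefined ratios (empty denominator) are returned as `NA`.
#' @export
confusion_metrics <- function(predicted, labels) {
  y <- as_binary(labels)
  p <- as_binary(predicted)
  tp <- sum(p == 1 & y == 1)
  tn <- sum(p == 0 & y == 0)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, accuracy = (tp + tn) / length(y))
}

#' The 20-model architecture x hyperparameter grid
#'
#' Four architectures, each with a 5-value hyperparameter grid: L1-penalized
#' logistic regression (penalty strength C), linear-kernel SVM (C),
#' RBF-kernel SVM (C) and random forest (tree count). Every model carries a
#' seed derived from `seed`.
#'
#' @param seed Integer seed.
#' @param c_grid Penalty values for the logistic and SVM models.
#' @param tree_grid Tree counts for the random forest.
#' @return Tibble with `model_id`, `architecture`, `hyperparameter`,
#'   `value`, `seed`.
#' @export
build_model_grid <- function(seed = 1, c_grid = c(0.01, 0.1, 1, 10, 100),
                             tree_grid = c(50, 100, 200, 400, 800)) {
  stopifnot(length(c_grid) >= 1, length(tree_grid) >= 1)
  archs <- list(lr_l1 = c_grid, svm_linear = c_grid, svm_rbf = c_grid,
                rf = tree_grid)
  rows <- purrr::imap(archs, function(vals, arch) {
    tibble::tibble(architecture = arch,
                   hyperparameter = if (arch == "rf") "num_trees" else "C",
                   value = vals)
  })
  grid <- dplyr::bind_rows(rows)
  grid$model_id <- sprintf("%s_%g", grid$architecture, grid$value)
  grid$seed <- participant_seed(seed, seq_len(nrow(grid)), stream = 77L)
  grid[, c("model_id", "architecture", "hyperparameter", "value", "seed")]
}

#' Fit one classifier from the model grid
#'
#' @param spec One row of [build_model_grid()].
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @return A fitted model wrapper of class `ogtt_classifier`.
#' @export
fit_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  yb <- as_binary(y)
  fit <- switch(
    spec$architecture,
    lr_l1 = {
      # C is the inverse penalty strength; glmnet's lambda = 1/(n*C)
      glmnet::glmnet(X, yb, family = "binomial", alpha = 1,
                     lambda = 1 / (nrow(X) * spec$value),
                     standardize = TRUE, maxit = 1e5)
    },
    svm_linear = ,
    svm_rbf = {
      kern <- if (spec$architecture == "svm_rbf") "radial" else "linear"
      # constant columns (e.g. a rare one-hot level absent from a fold)
      # trigger a harmless scaling warning
      with_seed(spec$seed, suppressWarnings(
        e1071::svm(X, factor(yb, levels = c(0, 1)), kernel = kern,
                   cost = spec$value, scale = TRUE)))
    },
    rf = {
      df <- data.frame(X)
      df$.y <- factor(yb, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, num.trees = spec$value,
                     probability = TRUE, seed = spec$seed, num.threads = 1)
    },
    stop("unknown architecture: ", spec$architecture))
  orient <- 1
  if (spec$architecture %in% c("svm_linear", "svm_rbf")) {
    # decision-value sign depends on which class e1071 saw first; orient so
    # higher margin means class 1, using the training data
    dv <- attr(stats::predict(fit, X, decision.values = TRUE),
               "decision.values")[, 1]
    if (sum(yb == 1) > 0 && sum(yb == 0) > 0 &&
        mean(dv[yb == 1]) < mean(dv[yb == 0])) {
      orient <- -1
    }
  }
  structure(list(spec = spec, fit = fit, orient = orient,
                 columns = colnames(X)),
            class = "ogtt_classifier")
}

#' Continuous classifier scores (probability or margin)
#'
#' Predicted class-1 probability for the logistic and forest models;
#' decision-function margin (oriented so higher = class 1) for the SVMs.
#'
#' @param model An [fit_classifier()] object.
#' @param X Feature matrix.
#' @return Numeric scores.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)[, model$columns, drop = FALSE]
  switch(
    model$spec$architecture,
    lr_l1 = drop(stats::predict(model$fit, X, type = "response")),
    svm_linear = ,
    svm_rbf = model$orient *
      attr(stats::predict(model$fit, X, decision.values = TRUE),
           "decision.values")[, 1],
    rf = stats::predict(model$fit, data.frame(X),
                        num.threads = 1)$predictions[, "1"])
}

predict_classes <- function(model, X, threshold = 0.5) {
  scores <- predict_scores(model, X)
  cut <- if (model$spec$architecture %in% c("svm_linear", "svm_rbf")) 0
         else threshold
  as.integer(scores >= cut)
}

stratified_folds <- function(y, k) {
  y <- as_binary(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class ", cls, " has fewer than k = ", k, " members",
           call. = FALSE)
    }
    idx <- sample(idx)                     # uses the caller's RNG stream
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation over a model grid
#'
#' Per repeat the data are shuffled and split into `k` stratified folds;
#' every model is fitted on k-1 folds and scored on the held-out fold. When
#' `curve_matrix` is supplied (reduced-representation feature set), the PCA
#' basis is re-fitted inside each training fold and the validation curves
#' are projected through it, so no information leaks from held-out curves.
#'
#' @param X Numeric feature matrix (the static columns; may have 0 columns
#'   when the feature set is purely curve-derived).
#' @param y Binary labels, one per row of `X`.
#' @param models Tibble from [build_model_grid()].
#' @param k Folds (default 5).
#' @param repeats Shuffle-and-split repetitions (default 100).
#' @param seed Integer seed.
#' @param curve_matrix Optional matrix of preprocessed curves (rows aligned
#'   with `X`) whose fold-wise PC scores are appended to the features.
#' @return Tibble of per-model, per-repeat, per-fold metrics.
#' @export
repeated_stratified_cv <- function(X, y, models, k = 5, repeats = 100,
                                   seed = 1, curve_matrix = NULL) {
  X <- as.matrix(X)
  yb <- as_binary(y)
  stopifnot(nrow(X) == length(yb))
  if (!is.null(curve_matrix)) {
    curve_matrix <- as.matrix(curve_matrix)
    stopifnot(nrow(curve_matrix) == length(yb))
  }
  out <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    fold <- with_seed(participant_seed(seed, rep_i, stream = 11L),
                      stratified_folds(yb, k))
    fold_rows <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold != f
      va <- !tr
      Xtr <- X[tr, , drop = FALSE]
      Xva <- X[va, , drop = FALSE]
      if (!is.null(curve_matrix)) {
        basis <- fit_reduced_rep(curve_matrix[tr, , drop = FALSE])
        Ztr <- project_reduced_rep(basis, curve_matrix[tr, , drop = FALSE])
        Zva <- project_reduced_rep(basis, curve_matrix[va, , drop = FALSE])
        colnames(Ztr) <- colnames(Zva) <- c("pc1", "pc2")
        Xtr <- cbind(Xtr, Ztr)
        Xva <- cbind(Xva, Zva)
      }
      rows <- lapply(seq_len(nrow(models)), function(m) {
        fit <- fit_classifier(models[m, ], Xtr, yb[tr])
        scores <- predict_scores(fit, Xva)
        cls <- predict_classes(fit, Xva)
        met <- confusion_metrics(cls, yb[va])
        tibble::tibble(model_id = models$model_id[m], rep = rep_i, fold = f,
                       auroc = auroc(scores, yb[va]),
                       sensitivity = met$sensitivity,
                       specificity = met$specificity,
                       precision = met$precision, f1 = met$f1,
                       accuracy = met$accuracy)
      })
      fold_rows[[f]] <- dplyr::bind_rows(rows)
    }
    out[[rep_i]] <- dplyr::bind_rows(fold_rows)
  }
  dplyr::bind_rows(out)
}

#' Aggregate cross-validation metrics per model
#'
#' @param results Tibble from [repeated_stratified_cv()].
#' @return Tibble with per-model means and SDs of every metric.
#' @export
summarize_cv_results <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$model_id),
    dplyr::across(c("auroc", "sensitivity", "specificity", "precision",
                    "f1", "accuracy"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~stats::sd(.x, na.rm = TRUE))),
    .groups = "drop")
}

#' Select the best model from cross-validation results
#'
#' `"auroc"` picks the highest mean CV auROC; `"f1_sensitivity"` orders
#' lexicographically by mean F1 then mean sensitivity. Ties go to the
#' simpler model (smaller penalty C / fewer trees).
#'
#' @param results Tibble from [repeated_stratified_cv()].
#' @param models The model grid the results refer to.
#' @param criterion `"auroc"` (default) or `"f1_sensitivity"`.
#' @return The winning row of `models`.
#' @export
select_model <- function(results, models,
                         criterion = c("auroc", "f1_sensitivity")) {
  criterion <- match.arg(criterion)
  if (nrow(results) == 0) stop("empty CV results", call. = FALSE)
  agg <- summarize_cv_results(results)
  agg <- dplyr::left_join(agg, models, by = "model_id")
  ord <- if (criterion == "auroc") {
    order(-agg$auroc_mean, agg$value)
  } else {
    order(-agg$f1_mean, -agg$sensitivity_mean, agg$value)
  }
  models[models$model_id == agg$model_id[ord[1]], ]
}

#' Evaluate a fitted model on a held-out test set
#'
#' @param model An [fit_classifier()] object.
#' @param X_test,y_test Held-out features and labels.
#' @param threshold Probability threshold for class predictions
#'   (margin models threshold at 0).
#' @return One-row tibble of auROC plus confusion metrics. auROC is `NA`
#'   when the test set has a single class.
#' @export
evaluate_on_test <- function(model, X_test, y_test, threshold = 0.5) {
  yb <- as_binary(y_test)
  if (length(yb) == 0) stop("empty test set", call. = FALSE)
  scores <- predict_scores(model, X_test)
  cls <- predict_classes(model, X_test, threshold)
  met <- confusion_metrics(cls, yb)
  tibble::tibble(auroc = auroc(scores, yb),
                 sensitivity = met$sensitivity,
                 specificity = met$specificity,
                 precision = met$precision, f1 = met$f1,
                 accuracy = met$accuracy)
}

#' Compare two auROC distributions (rank-sum with Bonferroni)
#'
#' Two-sided Wilcoxon rank-sum test on cross-validation auROC samples;
#' the adjusted p-value is `min(1, p * n_comparisons)`.
#'
#' @param dist_a,dist_b Numeric auROC samples.
#' @param n_comparisons Number of simultaneous comparisons (default 1).
#' @return List: `statistic`, `p_value`, `p_adjusted`.
#' @export
compare_auroc <- function(dist_a, dist_b, n_comparisons = 1) {
  if (length(dist_a) == 0 || length(dist_b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(dist_a, dist_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_comparisons))
}
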