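test_that("auROC equals the brute-force concordant-pair fraction", {
  withr::with_seed(19, {
    for (i in 1:40) {
      n <- sample(4:12, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
      s <- sample(seq_len(5), n, replace = TRUE) + rnorm(n, 0, 0.01)
      expect_equal(auroc(s, y), brute_auroc(s, y), tolerance = 1e-12)
    }
  })
  expect_equal(auroc(c(0.9, 0.6, 0.7, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_true(is.na(auroc(c(0.1, 0.9), c(1, 1))))
})

test_that("confusion metrics cover perfect and degenerate predictions", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1,
                            precision = 1, f1 = 1, accuracy = 1))
  allpos <- confusion_metrics(rep(1, 4), c(1, 1, 0, 0))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
})

test_that("the model grid spans 4 architectures x 5 hyperparameters", {
  g <- build_model_grid(seed = 3)
  expect_equal(nrow(g), 20)
  expect_equal(length(unique(g$architecture)), 4)
  expect_true(all(table(g$architecture) == 5))
  expect_identical(g, build_model_grid(seed = 3))
  g2 <- build_model_grid(seed = 4)
  expect_false(identical(g$seed, g2$seed))
})

test_that("stratified folds keep class proportions within one member", {
  withr::with_seed(7, {
    y <- rbinom(83, 1, 0.3)
    fold <- ogttpheno:::stratified_folds(y, 5)
    global <- mean(y)
    for (f in 1:5) {
      n_f <- sum(fold == f)
      expect_lte(abs(sum(y[fold == f]) - global * n_f), 1)
    }
    expect_error(ogttpheno:::stratified_folds(c(1, rep(0, 20)), 5),
                 "fewer than k")
  })
})

test_that("every architecture separates linearly separable data", {
  d <- separable_data()
  models <- build_model_grid(1)
  # mid-grid settings: the extreme penalty C = 0.01 rightly shrinks the
  # logistic model to its intercept, which is not what this test probes
  one_each <- models[models$model_id %in% c("lr_l1_1", "svm_linear_1",
                                            "svm_rbf_1", "rf_200"), ]
  cv <- repeated_stratified_cv(d$X, d$y, one_each, k = 5, repeats = 2,
                               seed = 2)
  agg <- summarize_cv_results(cv)
  expect_true(all(agg$auroc_mean > 0.95))
})

test_that("model selection follows auROC then the F1/sensitivity order", {
  models <- build_model_grid(1)[c(1, 2), ]
  fake <- function(id, auroc, f1, sens) {
    tibble::tibble(model_id = id, rep = 1, fold = 1:2, auroc = auroc,
                   sensitivity = sens, specificity = 0.5, precision = 0.5,
                   f1 = f1, accuracy = 0.5)
  }
  res <- rbind(fake(models$model_id[1], 0.9, 0.5, 0.5),
               fake(models$model_id[2], 0.8, 0.9, 0.9))
  expect_equal(select_model(res, models, "auroc")$model_id,
               models$model_id[1])
  expect_equal(select_model(res, models, "f1_sensitivity")$model_id,
               models$model_id[2])
  # F1 tie resolved by sensitivity
  res2 <- rbind(fake(models$model_id[1], 0.8, 0.7, 0.8),
                fake(models$model_id[2], 0.8, 0.7, 0.7))
  expect_equal(select_model(res2, models, "f1_sensitivity")$model_id,
               models$model_id[1])
  expect_error(select_model(res[0, ], models), "empty")
})

test_that("held-out evaluation returns the hand-counted auROC", {
  d <- separable_data(40)
  models <- build_model_grid(1)
  fit <- fit_classifier(models[models$model_id == "lr_l1_1", ], d$X, d$y)
  ev <- evaluate_on_test(fit, d$X, d$y)
  expect_gt(ev$auroc, 0.95)
  expect_gt(ev$accuracy, 0.9)
  scores <- predict_scores(fit, d$X)
  expect_equal(ev$auroc, brute_auroc(scores, d$y), tolerance = 1e-12)
  # single-class test set: auROC undefined, other metrics returned
  ev1 <- evaluate_on_test(fit, d$X[d$y == 1, ], d$y[d$y == 1])
  expect_true(is.na(ev1$auroc))
  expect_false(is.na(ev1$sensitivity))
})

test_that("cross-validation never sees held-out rows", {
  d <- separable_data(80, seed = 9)
  train <- seq_len(60)
  models <- build_model_grid(1)[c(1, 6), ]
  cv1 <- repeated_stratified_cv(d$X[train, ], d$y[train], models,
                                k = 5, repeats = 2, seed = 3)
  y_corrupt <- d$y
  y_corrupt[61:80] <- 1 - y_corrupt[61:80]
  cv2 <- repeated_stratified_cv(d$X[train, ], y_corrupt[train], models,
                                k = 5, repeats = 2, seed = 3)
  expect_identical(cv1, cv2)
})

test_that("rank-sum comparison applies the Bonferroni cap", {
  same <- rep(c(0.7, 0.8), 10)
  out <- compare_auroc(same, same, n_comparisons = 5)
  expect_equal(out$p_adjusted, 1)
  a <- seq(0.9, 0.99, length.out = 50)
  b <- seq(0.1, 0.19, length.out = 50)
  sep <- compare_auroc(a, b)
  expect_lt(sep$p_value, 1e-15)
  expect_equal(compare_auroc(a, b, n_comparisons = 1e20)$p_adjusted, 1)
  expect_error(compare_auroc(numeric(0), a), "nonempty")
})

test_that("feature sets always include demographics and build matrices", {
  specs <- feature_set_specs()
  expect_equal(length(specs), 9)
  expect_equal(sum(vapply(specs, function(s) s$use_curves, logical(1))), 1)
  prof <- tibble::tibble(participant_id = c("a", "b", "c"),
                         age = c(50, 60, 55), sex = c(0, 1, 0),
                         bmi = c(24, 30, 27),
                         ethnicity = c("x", "y", "x"),
                         family_history = c(TRUE, FALSE, FALSE),
                         prs = c(0.1, -0.2, 0.5))
  fm <- build_feature_matrix(prof, "Demographics+PRS")
  expect_true(all(c("age", "sex", "bmi", "family_history", "prs") %in%
                    colnames(fm$X)))
  expect_true(any(grepl("ethnicity_", colnames(fm$X))))
  expect_error(build_feature_matrix(prof, "Demographics+Lab"), "hba1c")
  expect_error(build_feature_matrix(prof, "nonsense"), "unknown")
})
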