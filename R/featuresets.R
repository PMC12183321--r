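#' The nine benchmark feature sets
#'
#' Demographics (age, sex, BMI, ethnicity, family history of T2D) appears in
#' every set; the others add the polygenic score, lab values (HbA1c, FPG),
#' 2-h incretin concentrations, one fasting surrogate (HOMA-B or HOMA-IR),
#' the Matsuda index, the 14 engineered curve features, or the 2-component
#' reduced curve representation (fitted fold-wise, never on held-out data).
#'
#' @return Named list; each element has `columns` (profile columns beyond
#'   demographics) and `use_curves` (whether the PCA curve representation is
#'   appended).
#' @export
feature_set_specs <- function() {
  list(
    "Demographics" = list(columns = character(0), use_curves = FALSE),
    "Demographics+PRS" = list(columns = "prs", use_curves = FALSE),
    "Demographics+Lab" = list(columns = c("hba1c", "fpg"),
                              use_curves = FALSE),
    "Demographics+Incretins" = list(columns = c("gip_2h", "glp1_2h"),
                                    use_curves = FALSE),
    "Demographics+HOMA-B" = list(columns = "homa_b", use_curves = FALSE),
    "Demographics+HOMA-IR" = list(columns = "homa_ir", use_curves = FALSE),
    "Demographics+Matsuda" = list(columns = "matsuda", use_curves = FALSE),
    "Demographics+OGTT_G_Features" = list(
      columns = c("g_0", "g_60", "g_120", "g_180", "g_peak", "curve_size",
                  "auc", "pauc", "nauc", "iauc", "cv", "t_baseline2peak",
                  "s_baseline2peak", "s_peak2end"),
      use_curves = FALSE),
    "Demographics+OGTT_G_ReducedRep" = list(columns = character(0),
                                            use_curves = TRUE))
}

demographic_columns <- function() {
  c("age", "sex", "bmi", "family_history")
}

#' Build the numeric feature matrix for one feature set
#'
#' One-hot-encodes ethnicity, binds the demographic columns and the set's
#' extra columns.
#'
#' @param profiles Profile tibble (one row per participant).
#' @param set_name Name from [feature_set_specs()].
#' @return List: `X` (numeric matrix), `use_curves` (logical).
#' @export
build_feature_matrix <- function(profiles, set_name) {
  specs <- feature_set_specs()
  if (!set_name %in% names(specs)) {
    stop("unknown feature set: ", set_name, call. = FALSE)
  }
  spec <- specs[[set_name]]
  cols <- c(demographic_columns(), spec$columns)
  miss <- setdiff(cols, names(profiles))
  if (length(miss) > 0) {
    stop("profiles lack feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(dplyr::mutate(profiles[, cols],
                               dplyr::across(dplyr::everything(),
                                             as.numeric)))
  if ("ethnicity" %in% names(profiles)) {
    eth <- factor(profiles$ethnicity)
    if (nlevels(eth) > 1) {
      E <- stats::model.matrix(~ eth - 1)
      colnames(E) <- paste0("ethnicity_", levels(eth))
      X <- cbind(X, E[, -1, drop = FALSE])   # reference-coded
    }
  }
  list(X = X, use_curves = spec$use_curves)
}

#' Stratified train/test split of a cohort
#'
#' @param y Binary labels.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Integer seed.
#' @param split_by Optional logical vector: `TRUE` rows go to training
#'   regardless (e.g. participants without CGM data); overrides the random
#'   split.
#' @return Logical vector, `TRUE` = training row.
#' @export
train_test_split <- function(y, test_fraction = 0.2, seed = 1,
                             split_by = NULL) {
  yb <- as_binary(y)
  if (!is.null(split_by)) return(as.logical(split_by))
  train <- rep(TRUE, length(yb))
  with_seed(participant_seed(seed, 1L, stream = 5L), {
    for (cls in unique(yb)) {
      idx <- which(yb == cls)
      n_test <- max(1, round(length(idx) * test_fraction))
      train[sample(idx, n_test)] <- FALSE
    }
  })
  train
}

#' Benchmark every feature set against every metabolic subphenotype
#'
#' For each phenotype x feature set: stratified train/test split, 20-model
#' grid, repeated stratified cross-validation on the training set, selection
#' of the best model by mean CV auROC, refit on the full training set and
#' evaluation on the held-out test set. The reduced-representation basis is
#' always fitted on training rows only.
#'
#' @param profiles Profile tibble with demographics, markers, curve features
#'   and binary label columns.
#' @param curves Matrix of preprocessed curves (rows aligned with
#'   `profiles`), required for the reduced-representation set.
#' @param phenotypes Label columns to predict (default the four binary
#'   subphenotype flags).
#' @param feature_sets Names from [feature_set_specs()] (default all nine).
#' @param protocol List: `k`, `repeats`, `seed`, `test_fraction`,
#'   `selection`.
#' @return Tibble, one row per phenotype x feature set, with the selected
#'   classifier, its mean CV auROC, and test-set metrics; failed sets are
#'   reported in the `error` column and do not abort the others.
#' @export
benchmark_feature_sets <- function(profiles, curves = NULL,
                                   phenotypes = c("muscle_ir",
                                                  "beta_dysfunction",
                                                  "incretin_dysfunction",
                                                  "hepatic_ir_flag"),
                                   feature_sets = names(feature_set_specs()),
                                   protocol = list()) {
  proto <- utils::modifyList(list(k = 5, repeats = 100, seed = 1,
                                  test_fraction = 0.2, selection = "auroc"),
                             protocol)
  models <- build_model_grid(proto$seed)
  rows <- list()
  for (ph in phenotypes) {
    y <- as_binary(profiles[[ph]])
    train <- train_test_split(y, proto$test_fraction, proto$seed)
    for (fs in feature_sets) {
      row <- tryCatch({
        fm <- build_feature_matrix(profiles, fs)
        cm <- if (fm$use_curves) {
          if (is.null(curves)) stop("curve matrix required for ", fs)
          as.matrix(curves)
        } else NULL
        cv <- repeated_stratified_cv(
          fm$X[train, , drop = FALSE], y[train], models,
          k = proto$k, repeats = proto$repeats, seed = proto$seed,
          curve_matrix = if (is.null(cm)) NULL
                         else cm[train, , drop = FALSE])
        best <- select_model(cv, models, proto$selection)
        cv_mean <- summarize_cv_results(cv)
        cv_auroc <- cv_mean$auroc_mean[cv_mean$model_id == best$model_id]
        Xtr <- fm$X[train, , drop = FALSE]
        Xte <- fm$X[!train, , drop = FALSE]
        if (!is.null(cm)) {
          basis <- fit_reduced_rep(cm[train, , drop = FALSE])
          Ztr <- project_reduced_rep(basis, cm[train, , drop = FALSE])
          Zte <- project_reduced_rep(basis, cm[!train, , drop = FALSE])
          colnames(Ztr) <- colnames(Zte) <- c("pc1", "pc2")
          Xtr <- cbind(Xtr, Ztr)
          Xte <- cbind(Xte, Zte)
        }
        fit <- fit_classifier(best, Xtr, y[train])
        test_met <- evaluate_on_test(fit, Xte, y[!train])
        dplyr::bind_cols(
          tibble::tibble(phenotype = ph, feature_set = fs,
                         classifier = best$architecture,
                         hyperparameter = best$value,
                         cv_auroc = cv_auroc),
          test_met, tibble::tibble(error = NA_character_))
      }, error = function(e) {
        tibble::tibble(phenotype = ph, feature_set = fs,
                       classifier = NA_character_, hyperparameter = NA_real_,
                       cv_auroc = NA_real_, auroc = NA_real_,
                       sensitivity = NA_real_, specificity = NA_real_,
                       precision = NA_real_, f1 = NA_real_,
                       accuracy = NA_real_, error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
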