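#' Default model-search grid
#'
#' The model search used by [fit_classifier()] is a pluggable interface: a
#' list of candidate specifications, each with a `name`, a
#' `fit(data, label)` function and a `predict(model, newdata)` function
#' returning class labels. The default grid covers three standard
#' classifier families — logistic regression, random forest, and an
#' RBF-kernel SVM — with fixed, modest hyperparameters; no ensembling is
#' performed (model averaging is deliberately avoided to limit
#' overfitting).
#'
#' @return A list of model specifications.
#' @export
default_model_search <- function() {
  list(
    list(
      name = "logistic",
      fit = function(data, label) {
        if (nlevels(data[[label]]) != 2) return(NULL)
        fml <- as.formula(paste0("`", label, "` ~ ."))
        suppressWarnings(glm(fml, data = data, family = binomial()))
      },
      predict = function(model, newdata, levels) {
        p <- predict(model, newdata = newdata, type = "response")
        factor(ifelse(p > 0.5, levels[2], levels[1]), levels = levels)
      }
    ),
    list(
      name = "random_forest",
      fit = function(data, label) {
        fml <- as.formula(paste0("`", label, "` ~ ."))
        randomForest::randomForest(fml, data = data, ntree = 200)
      },
      predict = function(model, newdata, levels) {
        factor(predict(model, newdata = newdata), levels = levels)
      }
    ),
    list(
      name = "svm_rbf",
      fit = function(data, label) {
        fml <- as.formula(paste0("`", label, "` ~ ."))
        e1071::svm(fml, data = data, kernel = "radial")
      },
      predict = function(model, newdata, levels) {
        factor(predict(model, newdata = newdata), levels = levels)
      }
    )
  )
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    if (length(idx) < k) {
      abort(sprintf("Class '%s' has fewer members (%d) than folds (%d).",
                    lv, length(idx), k))
    }
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a classifier with stratified cross-validated model selection
#'
#' Splits rows into stratified train/test sets, evaluates every candidate
#' in `model_search` by stratified `k_folds`-fold cross-validation on the
#' training set, selects the candidate with the highest CV accuracy (ties
#' break to the earlier candidate), refits it on the full training set, and
#' reports train and held-out test accuracy. Reproducible for a fixed
#' `seed`.
#'
#' @param table data frame: numeric feature columns plus the label column.
#' @param label name of the label column (factor or coercible; >= 2
#'   classes).
#' @param test_size held-out fraction (stratified).
#' @param k_folds cross-validation folds (default 3).
#' @param handle_missing `"drop_rows"` (drop incomplete rows) or
#'   `"mean_impute"` (impute feature NAs with training-set means).
#' @param model_search candidate list, see [default_model_search()].
#' @param seed integer seed controlling the split, folds and model fits.
#' @return An object of class `classifier_fit`: `model_name`, `model`,
#'   `cv_results` (per-candidate CV accuracy), `train_accuracy`,
#'   `test_accuracy`, `features`, `label`, `levels`, `test_data`, `seed`.
#' @export
fit_classifier <- function(table, label = "class", test_size = 0.25,
                           k_folds = 3,
                           handle_missing = c("drop_rows", "mean_impute"),
                           model_search = default_model_search(),
                           seed = 1L) {
  handle_missing <- match.arg(handle_missing)
  df <- as.data.frame(table)
  if (!label %in% names(df)) abort(sprintf("No label column '%s'.", label))
  df[[label]] <- droplevels(as.factor(df[[label]]))
  if (nlevels(df[[label]]) < 2) abort("Need >= 2 classes.")
  features <- setdiff(names(df), label)

  withr::with_seed(as.integer(seed), {
    if (handle_missing == "drop_rows") {
      df <- df[complete.cases(df), , drop = FALSE]
      impute_means <- NULL
    }
    y <- df[[label]]
    # stratified test split
    test_idx <- unlist(lapply(levels(y), function(lv) {
      idx <- sample(which(y == lv))
      head(idx, round(length(idx) * test_size))
    }))
    if (length(test_idx) == 0 || length(test_idx) == nrow(df)) {
      abort("test_size leaves an empty train or test set.")
    }
    train <- df[-test_idx, , drop = FALSE]
    test <- df[test_idx, , drop = FALSE]
    if (handle_missing == "mean_impute") {
      impute_means <- purrr::map_dbl(train[features], ~ mean(.x, na.rm = TRUE))
      train[features] <- impute_na(train[features], impute_means)
      test[features] <- impute_na(test[features], impute_means)
    }
    lv <- levels(y)

    fold <- stratified_folds(train[[label]], k_folds)
    cv_results <- purrr::map_dfr(model_search, function(spec) {
      accs <- purrr::map_dbl(seq_len(k_folds), function(f) {
        fit <- spec$fit(train[fold != f, , drop = FALSE], label)
        if (is.null(fit)) return(NA_real_)
        pred <- spec$predict(fit, train[fold == f, features, drop = FALSE], lv)
        mean(pred == train[[label]][fold == f])
      })
      tibble(model = spec$name, cv_accuracy = mean(accs))
    })
    if (all(is.na(cv_results$cv_accuracy))) {
      abort("No model in the search grid could be fitted.")
    }
    best_i <- which.max(cv_results$cv_accuracy)
    spec <- model_search[[best_i]]
    model <- spec$fit(train, label)
    pred_tr <- spec$predict(model, train[features], lv)
    pred_te <- spec$predict(model, test[features], lv)
    structure(
      list(
        model_name = spec$name, model = model, spec = spec,
        cv_results = cv_results,
        train_accuracy = mean(pred_tr == train[[label]]),
        test_accuracy = mean(pred_te == test[[label]]),
        features = features, label = label, levels = lv,
        impute_means = impute_means,
        train_data = as_tibble(train), test_data = as_tibble(test),
        seed = as.integer(seed)
      ),
      class = "classifier_fit"
    )
  })
}

impute_na <- function(df, means) {
  for (j in names(df)) {
    df[[j]][is.na(df[[j]])] <- means[[j]]
  }
  df
}

#' @export
print.classifier_fit <- function(x, ...) {
  cat(sprintf(
    "<classifier_fit> %s | train acc %.3f | test acc %.3f | %d features\n",
    x$model_name, x$train_accuracy, x$test_accuracy, length(x$features)
  ))
  invisible(x)
}

#' @export
predict.classifier_fit <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[object$features]
  if (!is.null(object$impute_means)) nd <- impute_na(nd, object$impute_means)
  object$spec$predict(object$model, nd, object$levels)
}

#' @export
tidy.classifier_fit <- function(x, ...) x$cv_results

#' @export
glance.classifier_fit <- function(x, ...) {
  tibble(
    model = x$model_name,
    train_accuracy = x$train_accuracy,
    test_accuracy = x$test_accuracy,
    n_train = nrow(x$train_data), n_test = nrow(x$test_data),
    n_features = length(x$features)
  )
}

#' Majority-label baseline accuracy
#'
#' For each of `repeats` repetitions of stratified `k_folds`-fold
#' cross-validation, the baseline predicts each evaluation fold with the
#' most frequent label of its training folds. Accuracy is aggregated over
#' the `repeats x k_folds` fold evaluations (mean ± SD of the fold-level
#' accuracies); per-repetition pooled accuracies are also returned.
#'
#' @param table data frame with the label column.
#' @param label label column name.
#' @param k_folds folds per repetition (default 5).
#' @param repeats number of repetitions (default 10).
#' @param seed integer seed.
#' @return A list: `mean`, `sd`, `per_repeat` (accuracy per repetition),
#'   `fold_accuracies` (tibble `repeat`, `fold`, `accuracy`).
#' @export
majority_baseline <- function(table, label = "class", k_folds = 5,
                              repeats = 10, seed = 1L) {
  df <- as.data.frame(table)
  y <- droplevels(as.factor(df[[label]]))
  withr::with_seed(as.integer(seed), {
    fold_rows <- purrr::map_dfr(seq_len(repeats), function(r) {
      fold <- stratified_folds(y, k_folds)
      purrr::map_dfr(seq_len(k_folds), function(f) {
        train_y <- y[fold != f]
        maj <- names(which.max(base::table(train_y)))
        tibble(
          rep = r, fold = f,
          n_eval = sum(fold == f),
          accuracy = mean(y[fold == f] == maj)
        )
      })
    })
    per_repeat <- fold_rows %>%
      group_by(.data$rep) %>%
      summarise(
        accuracy = sum(.data$accuracy * .data$n_eval) / sum(.data$n_eval),
        .groups = "drop"
      ) %>%
      pull(.data$accuracy)
    list(
      mean = mean(fold_rows$accuracy),
      sd = sd(fold_rows$accuracy),
      per_repeat = per_repeat,
      fold_accuracies = fold_rows %>% select("rep", "fold", "accuracy")
    )
  })
}

#' Permutation feature importance
#'
#' For each feature and each repeat, the feature's values in the held-out
#' data are shuffled, the model's accuracy recomputed, and the importance
#' sample recorded as `baseline accuracy - permuted accuracy`. Importance is
#' the mean over repeats; raw samples are kept to show the spread.
#'
#' @param fit a [fit_classifier()] result.
#' @param newdata evaluation rows (default: the fit's held-out test set).
#' @param repeats permutation repeats per feature (default 30).
#' @param seed integer seed.
#' @return An object of class `importance_result`: `samples` (tibble
#'   `feature`, `rep`, `importance`), `summary` (per-feature mean and sd),
#'   `baseline_accuracy`, `model_name`, `repeats`, `seed`.
#' @export
permutation_importance <- function(fit, newdata = NULL, repeats = 30,
                                   seed = 1L) {
  stopifnot(inherits(fit, "classifier_fit"))
  nd <- as.data.frame(newdata %||% fit$test_data)
  y <- factor(nd[[fit$label]], levels = fit$levels)
  base_acc <- mean(predict(fit, nd) == y)
  withr::with_seed(as.integer(seed), {
    samples <- purrr::map_dfr(fit$features, function(f) {
      purrr::map_dfr(seq_len(repeats), function(r) {
        perm <- nd
        perm[[f]] <- sample(perm[[f]])
        tibble(
          feature = f, rep = r,
          importance = base_acc - mean(predict(fit, perm) == y)
        )
      })
    })
    summary <- samples %>%
      group_by(.data$feature) %>%
      summarise(
        mean_importance = mean(.data$importance),
        sd_importance = sd(.data$importance),
        .groups = "drop"
      ) %>%
      arrange(dplyr::desc(.data$mean_importance))
    structure(
      list(
        samples = samples, summary = summary,
        baseline_accuracy = base_acc, model_name = fit$model_name,
        repeats = as.integer(repeats), seed = as.integer(seed)
      ),
      class = "importance_result"
    )
  })
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf(
    "<importance_result> %s | baseline acc %.3f | %d repeats\n",
    x$model_name, x$baseline_accuracy, x$repeats
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.importance_result <- function(x, ...) x$summary

#' Plot permutation-importance distributions
#'
#' Dot distribution of per-repeat accuracy drops per feature, features
#' ordered by mean importance.
#'
#' @param object an `importance_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.importance_result <- function(object, ...) {
  ord <- object$summary$feature
  df <- object$samples %>%
    mutate(feature = factor(.data$feature, levels = rev(ord)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_jitter(height = 0.15, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", color = "red", size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "accuracy drop on permutation", y = NULL,
      title = "Permutation feature importance",
      subtitle = sprintf(
        "%s, baseline accuracy %.3f, %d repeats",
        object$model_name, object$baseline_accuracy, object$repeats
      )
    )
}

#' Two-group Mann-Whitney U comparison
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: the exact null
#' distribution is used for small samples (`n_A * n_B <= 400` and no ties),
#' otherwise the normal approximation with tie correction and continuity
#' correction. Medians and interquartile ranges of both groups are reported
#' as display statistics.
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return A one-row tibble: `U` (number of (a, b) pairs with a > b),
#'   `p_value`, `exact`, `median_a`, `iqr_a`, `median_b`, `iqr_b`,
#'   `n_a`, `n_b`.
#' @export
group_compare <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups need at least one value.")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) * length(b) <= 400 && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(
    U = unname(ht$statistic),
    p_value = ht$p.value,
    exact = exact,
    median_a = median(a), iqr_a = stats::IQR(a),
    median_b = median(b), iqr_b = stats::IQR(b),
    n_a = length(a), n_b = length(b)
  )
}
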