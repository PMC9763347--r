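#' Stratified train/test split of a feature matrix
#'
#' Randomly selects `train_fraction` of the rows from each group for
#' training (rounding to the nearest count); remaining rows form the test
#' set. The split is a disjoint, exhaustive partition and is reproducible
#' from `seed`.
#'
#' @param features A [feature_matrix()].
#' @param train_fraction Fraction of each group used for training
#'   (default 0.67).
#' @param seed Optional integer seed.
#'
#' @return A list with tibbles `train` and `test`.
#' @export
split_features <- function(features, train_fraction = 0.67, seed = NULL) {
  check_scalar_number(train_fraction, "train_fraction", lower = 1e-9,
                      upper = 1 - 1e-9)
  groups <- unique(features$group)
  if (length(groups) != 2) {
    abort("`features` must contain exactly two groups.",
          class = "pw_domain_error")
  }
  counts <- table(features$group)
  if (any(counts < 3)) {
    abort("Each group needs at least 3 subjects to split.",
          class = "pw_domain_error")
  }
  idx <- with_seed_(seed, {
    unlist(lapply(groups, function(g) {
      rows <- which(features$group == g)
      n_train <- round(train_fraction * length(rows))
      n_train <- max(1, min(length(rows) - 1, n_train))
      sample(rows, n_train)
    }))
  })
  list(train = features[sort(idx), ],
       test = features[setdiff(seq_len(nrow(features)), idx), ])
}

#' Youden-index threshold for predicted probabilities
#'
#' Evaluates `gamma = (sensitivity + specificity - 1) / sqrt(2)` at every
#' distinct predicted probability as a candidate threshold (predicting
#' "case" when probability >= threshold) and returns the maximizer; ties go
#' to the smallest threshold. Geometrically this is the ROC point most
#' distant from the diagonal.
#'
#' @param probabilities Numeric vector of predicted case probabilities.
#' @param labels Logical vector (or factor/character coercible via
#'   `labels == "case"`): `TRUE` for cases.
#'
#' @return A list with `threshold` and `gamma`.
#' @export
#'
#' @examples
#' youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
youden_threshold <- function(probabilities, labels) {
  y <- as_case_logical(labels)
  if (length(probabilities) != length(y)) {
    abort("`probabilities` and `labels` must have equal length.",
          class = "pw_domain_error")
  }
  if (!any(y) || all(y)) {
    abort("Both classes must be present.", class = "pw_domain_error")
  }
  cand <- sort(unique(probabilities))
  gam <- vapply(cand, function(thr) {
    pred <- probabilities >= thr
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    (sens + spec - 1) / sqrt(2)
  }, numeric(1))
  # near-ties (floating-point noise on rationally equal gammas) go to the
  # smallest threshold
  best <- which(gam >= max(gam) - 1e-12)[1]
  list(threshold = cand[best], gamma = gam[best])
}

#' ROC curve from predicted probabilities
#'
#' Monotone staircase of (false positive rate, true positive rate) pairs over
#' all distinct thresholds, from (0, 0) to (1, 1).
#'
#' @inheritParams youden_threshold
#'
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(probabilities, labels) {
  y <- as_case_logical(labels)
  if (!any(y) || all(y)) {
    abort("Both classes must be present.", class = "pw_domain_error")
  }
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  out <- purrr::map(thr, function(t) {
    pred <- probabilities >= t
    tibble(threshold = t,
           fpr = sum(pred & !y) / sum(!y),
           tpr = sum(pred & y) / sum(y))
  })
  dplyr::bind_rows(out)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; equals the Mann-Whitney U statistic
#' divided by `n_case * n_control` (up to tie handling by midranks).
#'
#' @inheritParams youden_threshold
#' @return A number in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  rc <- roc_curve(probabilities, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "case")
  if (is.numeric(labels)) return(labels != 0)
  abort("Cannot interpret `labels`.", class = "pw_domain_error")
}

#' Train and evaluate classifiers on a feature matrix
#'
#' Fits each requested model on a stratified train split restricted to the
#' selected features, and reports sensitivity, specificity and accuracy on
#' the held-out test split ("case" is the positive class). Logistic
#' regression is thresholded by the Youden index computed on the *training*
#' predictions (selecting the threshold on test data would leak); SVM and
#' KNN use their native decision rules.
#'
#' Missing feature entries are median-imputed: within group on the training
#' split, and with the pooled training medians on the test split. Features
#' are z-scored with training means/SDs before SVM and KNN.
#'
#' @param features A [feature_matrix()].
#' @param selected Integer indices of the features to use (e.g. from
#'   [select_features()]); `NULL` uses all features.
#' @param models Subset of `c("lr", "svm", "knn")`.
#' @param train_fraction Stratified split fraction (default 0.67).
#' @param seed Optional integer seed controlling the split.
#' @param knn_k Neighbourhood size for KNN (default 5).
#' @param standardize Whether to z-score features for SVM/KNN (default TRUE).
#'
#' @return A tibble of class `pw_evaluation`: one row per model with columns
#'   `model`, `sensitivity`, `specificity`, `accuracy` (percent),
#'   `threshold` (LR only), `n_train`, `n_test`, plus list-columns
#'   `confusion` (2x2 table) and `roc` (LR only).
#' @export
evaluate_models <- function(features, selected = NULL,
                            models = c("lr", "svm", "knn"),
                            train_fraction = 0.67, seed = NULL,
                            knn_k = 5, standardize = TRUE) {
  models <- match.arg(models, c("lr", "svm", "knn"), several.ok = TRUE)
  cols <- feature_cols(features)
  if (is.null(selected)) selected <- seq_along(cols)
  if (length(selected) == 0 || any(selected < 1 | selected > length(cols))) {
    abort("`selected` must be non-empty valid feature indices.",
          class = "pw_domain_error")
  }
  use_cols <- cols[selected]
  parts <- split_features(features, train_fraction, seed)
  train <- parts$train
  test <- parts$test
  y_train <- as_case_logical(train$group)
  y_test <- as_case_logical(test$group)

  X_train <- as.matrix(train[use_cols])
  X_test <- as.matrix(test[use_cols])
  imp <- impute_features(X_train, X_test, y_train)
  X_train <- imp$train
  X_test <- imp$test
  const <- apply(X_train, 2, function(v) sd(v) == 0)
  if (any(const)) {
    abort(paste0("Constant training feature(s): ",
                 paste(use_cols[const], collapse = ", ")),
          class = "pw_data_error")
  }
  Z <- if (standardize) {
    mu <- colMeans(X_train)
    s <- apply(X_train, 2, sd)
    list(train = sweep(sweep(X_train, 2, mu), 2, s, "/"),
         test = sweep(sweep(X_test, 2, mu), 2, s, "/"))
  } else {
    list(train = X_train, test = X_test)
  }

  rows <- purrr::map(models, function(mod) {
    res <- switch(mod,
      lr = fit_lr(X_train, y_train, X_test, y_test),
      svm = fit_svm(Z$train, y_train, Z$test, seed = seed),
      knn = fit_knn(Z$train, y_train, Z$test, k = knn_k, seed = seed)
    )
    cm <- table(
      predicted = factor(res$pred, levels = c(FALSE, TRUE),
                         labels = c("control", "case")),
      truth = factor(y_test, levels = c(FALSE, TRUE),
                     labels = c("control", "case"))
    )
    tp <- cm["case", "case"]; fn <- cm["control", "case"]
    tn <- cm["control", "control"]; fp <- cm["case", "control"]
    tibble(
      model = mod,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      accuracy = 100 * (tp + tn) / sum(cm),
      threshold = res$threshold %||% NA_real_,
      n_train = nrow(X_train),
      n_test = nrow(X_test),
      confusion = list(cm),
      roc = list(res$roc)
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("pw_evaluation", class(tibble())),
            seed = seed, selected = selected,
            train_fraction = train_fraction)
}

impute_features <- function(X_train, X_test, y_train) {
  pooled_med <- apply(X_train, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(X_train))) {
    for (grp in c(TRUE, FALSE)) {
      rows <- which(y_train == grp & is.na(X_train[, j]))
      if (length(rows) > 0) {
        gm <- median(X_train[y_train == grp, j], na.rm = TRUE)
        X_train[rows, j] <- if (is.na(gm)) pooled_med[j] else gm
      }
    }
    X_test[is.na(X_test[, j]), j] <- pooled_med[j]
  }
  list(train = X_train, test = X_test)
}

fit_lr <- function(X_train, y_train, X_test, y_test) {
  df_train <- as.data.frame(X_train)
  df_train$.y <- y_train
  fit <- suppressWarnings(
    glm(.y ~ ., data = df_train, family = binomial())
  )
  p_train <- suppressWarnings(predict(fit, type = "response"))
  thr <- youden_threshold(p_train, y_train)
  p_test <- suppressWarnings(
    predict(fit, newdata = as.data.frame(X_test), type = "response")
  )
  roc <- if (any(y_test) && !all(y_test)) roc_curve(p_test, y_test) else NULL
  list(pred = p_test >= thr$threshold, threshold = thr$threshold, roc = roc)
}

fit_svm <- function(Z_train, y_train, Z_test, seed = NULL) {
  fit <- with_seed_(seed, {
    e1071::svm(Z_train, factor(y_train, levels = c(FALSE, TRUE)),
               kernel = "radial")
  })
  pred <- predict(fit, Z_test)
  list(pred = as.logical(pred), threshold = NULL, roc = NULL)
}

fit_knn <- function(Z_train, y_train, Z_test, k = 5, seed = NULL) {
  k <- max(1L, min(as.integer(k), nrow(Z_train)))
  pred <- with_seed_(seed, {
    class::knn(Z_train, Z_test,
               cl = factor(y_train, levels = c(FALSE, TRUE)), k = k)
  })
  list(pred = as.logical(pred), threshold = NULL, roc = NULL)
}
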