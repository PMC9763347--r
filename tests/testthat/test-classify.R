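make_features <- function(n_case = 28, n_control = 22, sep = 2, seed = 42,
                          k = 4) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(n_case * k, mean = sep), n_case, k),
      matrix(rnorm(n_control * k, mean = 0), n_control, k)
    )
    fm <- tibble::as_tibble(as.data.frame(X))
    names(fm) <- sprintf("f_%03d", seq_len(k))
    fm <- dplyr::bind_cols(
      tibble::tibble(
        participant_id = sprintf("s%02d", seq_len(n_case + n_control)),
        group = rep(c("case", "control"), c(n_case, n_control))
      ),
      fm
    )
    structure(fm, class = c("feature_matrix", class(tibble::tibble())),
              n_windows = k)
  })
}

test_that("stratified split reproduces the 67/33 cohort arithmetic", {
  fm <- make_features(28, 22)
  parts <- split_features(fm, 0.67, seed = 42)
  train_counts <- table(parts$train$group)
  expect_equal(unname(train_counts[["case"]]), 19) # round(0.67 * 28)
  expect_equal(unname(train_counts[["control"]]), 15) # round(0.67 * 22)
  # disjoint and exhaustive
  expect_length(intersect(parts$train$participant_id,
                          parts$test$participant_id), 0)
  expect_setequal(c(parts$train$participant_id, parts$test$participant_id),
                  fm$participant_id)
  # deterministic given the seed
  parts2 <- split_features(fm, 0.67, seed = 42)
  expect_identical(parts$train$participant_id, parts2$train$participant_id)
  tiny <- fm[c(1:2, 29:30), ]
  expect_error(split_features(tiny, 0.67, 1), class = "pw_domain_error")
})

test_that("Youden threshold achieves gamma = 1/sqrt(2) under separation", {
  out <- youden_threshold(c(0.9, 0.8, 0.2, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE))
  expect_gt(out$threshold, 0.2)
  expect_lte(out$threshold, 0.8)
  expect_equal(out$gamma, 1 / sqrt(2))
})

test_that("Youden search equals exhaustive brute force", {
  set.seed(42)
  for (r in 1:30) {
    n <- 20
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    p <- round(runif(n), 2) # ties among candidate thresholds
    got <- youden_threshold(p, y)
    oracle <- youden_brute_force(p, y)
    expect_equal(got$gamma, oracle$gamma)
    expect_equal(got$threshold, oracle$threshold)
  }
})

test_that("uninformative probabilities give near-zero gamma", {
  set.seed(42)
  y <- rep(c(TRUE, FALSE), 500)
  p <- runif(1000)
  expect_lt(youden_threshold(p, y)$gamma, 0.1)
  expect_error(youden_threshold(p, rep(TRUE, 1000)),
               class = "pw_domain_error")
})

test_that("ROC curve is a staircase from (0,0) to (1,1)", {
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1)) # perfect separation
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # all-equal probabilities: two-point degenerate curve
  rc2 <- roc_curve(rep(0.5, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(rc2), 2)
})

test_that("AUC equals the Mann-Whitney statistic and the pROC oracle", {
  set.seed(42)
  for (r in 1:10) {
    y <- rep(c(TRUE, FALSE), c(12, 15))
    p <- rnorm(27)
    auc <- roc_auc(p, y)
    u <- mean(outer(p[y], p[!y], ">") + 0.5 * outer(p[y], p[!y], "=="))
    expect_equal(auc, u, tolerance = 1e-12)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = p, quiet = TRUE, direction = "<"
    )))
    expect_equal(auc, ref, tolerance = 1e-12)
  }
})

test_that("well-separated features are classified accurately by all models", {
  fm <- make_features(20, 20, sep = 3)
  res <- evaluate_models(fm, selected = 1:4, seed = 42)
  expect_setequal(res$model, c("lr", "svm", "knn"))
  expect_true(all(res$accuracy > 70))
  expect_false(is.na(res$threshold[res$model == "lr"]))
  # metrics recompute from the stored confusion matrices
  for (i in seq_len(nrow(res))) {
    cm <- res$confusion[[i]]
    expect_equal(res$sensitivity[i], cm["case", "case"] / sum(cm[, "case"]))
    expect_equal(res$specificity[i],
                 cm["control", "control"] / sum(cm[, "control"]))
    expect_equal(res$accuracy[i], 100 * sum(diag(cm)) / sum(cm))
  }
})

test_that("permuted labels drop accuracy to chance", {
  fm <- make_features(20, 20, sep = 3)
  fm$group <- withr::with_seed(42, sample(fm$group))
  res <- evaluate_models(fm, selected = 1:4, seed = 42)
  # balanced test set of 14: chance ~50%, binomial 3 SE ~ 40 points
  expect_true(all(res$accuracy >= 10 & res$accuracy <= 90))
})

test_that("KNN votes are invariant to duplicating the training set", {
  fm <- make_features(10, 10, sep = 1)
  Z_train <- as.matrix(fm[1:14, sprintf("f_%03d", 1:4)])
  y_train <- fm$group[1:14] == "case"
  Z_test <- as.matrix(fm[15:20, sprintf("f_%03d", 1:4)])
  # duplicating every training row doubles each neighbour's vote, so with
  # 2k neighbours the majority is unchanged (and cannot tie for odd k)
  p1 <- pupilwave:::fit_knn(Z_train, y_train, Z_test, k = 5, seed = 1)
  p2 <- pupilwave:::fit_knn(rbind(Z_train, Z_train),
                            c(y_train, y_train), Z_test, k = 10, seed = 1)
  expect_identical(p1$pred, p2$pred)
})

test_that("evaluation results are reproducible from the seed", {
  fm <- make_features(15, 15, sep = 1)
  r1 <- evaluate_models(fm, selected = 1:2, seed = 9)
  r2 <- evaluate_models(fm, selected = 1:2, seed = 9)
  expect_identical(dplyr::select(r1, -"confusion", -"roc"),
                   dplyr::select(r2, -"confusion", -"roc"))
})
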