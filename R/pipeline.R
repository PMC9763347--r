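#' Run the full feature-extraction and classification pipeline
#'
#' Executes the complete analysis on a long-format cohort table: clean
#' (compact missing samples, reject sessions with more than 80% missing),
#' segment each session into non-overlapping windows, estimate the wavelet
#' spectral slope of every window, average over each subject's sessions,
#' rank window positions by the Fisher criterion, select the top features,
#' and evaluate classifiers on a stratified train/test split.
#'
#' @param cohort Long cohort tibble (see [read_cohort()] or
#'   [simulate_cohort()]).
#' @param window_size Window length (power of two, default 1024).
#' @param wavelet Wavelet name (default `"db6"`).
#' @param n_levels Detail levels per window (default 5).
#' @param estimator Energy estimator (default distance variance).
#' @param n_features Number of Fisher-selected features (default 6; capped
#'   at the number of available windows).
#' @param models Classifiers to evaluate (default LR, SVM, KNN).
#' @param train_fraction Stratified split fraction (default 0.67).
#' @param max_missing_fraction Session rejection threshold (default 0.8).
#' @param seed Optional integer seed (controls the split only; the input
#'   cohort is data).
#'
#' @return An object of class `pw_pipeline`: a list with `config`,
#'   `cleaning` (per-session log), `slopes`, `features`, `fisher`,
#'   `selected` and `evaluation`.
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(
#'   cohort_spec(6, 6, H_case = 0.6, H_control = 0.95,
#'               session_length = 4096, sessions_per_subject = 2, seed = 1)
#' )
#' run_pipeline(cohort, n_features = 3, seed = 1)$evaluation
run_pipeline <- function(cohort, window_size = 1024, wavelet = "db6",
                         n_levels = 5, estimator = "distance_variance",
                         n_features = 6, models = c("lr", "svm", "knn"),
                         train_fraction = 0.67,
                         max_missing_fraction = 0.8, seed = NULL) {
  config <- list(
    window_size = window_size, wavelet = wavelet, n_levels = n_levels,
    estimator = as_energy_estimator(estimator)$kind,
    n_features = n_features, models = models,
    train_fraction = train_fraction,
    max_missing_fraction = max_missing_fraction, seed = seed
  )
  cleaning <- clean_sessions(cohort, max_missing_fraction)
  slopes <- window_slopes(
    cohort, window_size = window_size, wavelet = wavelet,
    n_levels = n_levels, estimator = estimator,
    max_missing_fraction = max_missing_fraction
  )
  features <- feature_matrix(slopes)
  fisher <- fisher_scores(features)
  m <- min(n_features, nrow(fisher))
  selected <- select_features(fisher, m)
  evaluation <- evaluate_models(
    features, selected = selected, models = models,
    train_fraction = train_fraction, seed = seed
  )
  structure(
    list(config = config,
         cleaning = dplyr::select(cleaning, -"values"),
         slopes = slopes, features = features, fisher = fisher,
         selected = selected, evaluation = evaluation),
    class = "pw_pipeline"
  )
}

#' @export
print.pw_pipeline <- function(x, ...) {
  cat("<pw_pipeline>\n")
  cat(sprintf(
    "  %d sessions (%d rejected), %d subjects, %d windows/subject\n",
    nrow(x$cleaning), sum(x$cleaning$rejected), nrow(x$features),
    attr(x$features, "n_windows")
  ))
  cat(sprintf("  selected features: %s\n",
              paste(x$selected, collapse = ", ")))
  print(dplyr::select(x$evaluation, "model", "sensitivity", "specificity",
                      "accuracy"))
  invisible(x)
}

#' Synthetic validation report
#'
#' Runs the two synthetic validation studies — the coefficient-contamination
#' robustness experiment and the fBm Hurst-recovery sweep — and returns
#' their result tables and summaries.
#'
#' @param n_replicates Replicates for both studies (default 200).
#' @param recovery_n fBm path length for the recovery sweep (default `2^14`).
#' @param seed Optional integer seed.
#' @param ... Further arguments passed to [contamination_experiment()].
#'
#' @return A list with elements `contamination` and `recovery`.
#' @export
run_validation <- function(n_replicates = 200, recovery_n = 2^14,
                           seed = NULL, ...) {
  list(
    contamination = contamination_experiment(
      n_replicates = n_replicates, seed = seed, ...
    ),
    recovery = hurst_recovery(
      n = recovery_n, n_replicates = n_replicates,
      seed = if (is.null(seed)) NULL else seed + 1L
    )
  )
}
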