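#' Clean a signal by compacting missing samples
#'
#' Removes missing samples (compaction, not interpolation), preserving the
#' order of the remaining samples. Signals whose missing fraction exceeds
#' `max_missing_fraction` are rejected.
#'
#' @param values Numeric vector.
#' @param missing Logical mask, same length (`NULL`: taken from `is.na`).
#' @param max_missing_fraction Rejection threshold (default 0.8: signals with
#'   more than 80% missing data are removed).
#'
#' @return A list with `values` (the compacted vector, or `NULL` if
#'   rejected), `rejected` (logical), and `missing_fraction`.
#' @export
#'
#' @examples
#' clean_signal(c(5.1, NA, 5.3, 5.2))
clean_signal <- function(values, missing = NULL, max_missing_fraction = 0.8) {
  if (is.null(missing)) missing <- is.na(values)
  if (length(missing) != length(values)) {
    abort("`values` and `missing` must have equal length.",
          class = "pw_domain_error")
  }
  frac <- mean(missing)
  if (frac > max_missing_fraction) {
    return(list(values = NULL, rejected = TRUE, missing_fraction = frac))
  }
  list(values = values[!missing], rejected = FALSE, missing_fraction = frac)
}

#' Clean all sessions of a cohort
#'
#' Applies [clean_signal()] to every (participant, session) signal of a long
#' cohort table.
#'
#' @param cohort Long cohort tibble (see [read_cohort()]).
#' @param max_missing_fraction Rejection threshold, as in [clean_signal()].
#'
#' @return A tibble with one row per session: `participant_id`, `group`,
#'   `session`, `n_raw`, `missing_fraction`, `rejected`, and a list-column
#'   `values` holding the compacted signal (`NULL` when rejected).
#' @export
clean_sessions <- function(cohort, max_missing_fraction = 0.8) {
  check_cohort_columns(cohort, "clean_sessions")
  missing <- if ("missing" %in% names(cohort)) cohort$missing
             else is.na(cohort$value)
  cohort <- dplyr::mutate(cohort, .missing = missing)
  out <- cohort |>
    dplyr::arrange(.data$participant_id, .data$session, .data$sample) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$session) |>
    dplyr::summarise(
      n_raw = dplyr::n(),
      cleaned = list(clean_signal(.data$value, .data$.missing,
                                  max_missing_fraction)),
      .groups = "drop"
    )
  dplyr::mutate(
    out,
    missing_fraction = purrr::map_dbl(.data$cleaned, "missing_fraction"),
    rejected = purrr::map_lgl(.data$cleaned, "rejected"),
    values = purrr::map(.data$cleaned, "values"),
    cleaned = NULL
  )
}

#' Segment a signal into non-overlapping windows
#'
#' Divides a cleaned signal into `floor(N / window_size)` consecutive
#' non-overlapping windows; the trailing remainder is discarded. For example
#' a 165,000-sample session with windows of 1024 yields 161 windows.
#'
#' @param x Numeric vector.
#' @param window_size Window length: a power of two, at least 64.
#'
#' @return A list of numeric vectors (empty, with a warning, if
#'   `length(x) < window_size`).
#' @export
#'
#' @examples
#' length(segment_windows(numeric(165000), 1024)) # 161
segment_windows <- function(x, window_size = 1024) {
  check_scalar_number(window_size, "window_size", lower = 64,
                      integerish = TRUE)
  if (!is_power_of_two(window_size)) {
    abort("`window_size` must be a power of two.", class = "pw_domain_error")
  }
  k <- length(x) %/% window_size
  if (k == 0) {
    warn(sprintf("Signal shorter than one window (%d < %d): no windows.",
                 length(x), window_size))
    return(list())
  }
  purrr::map(seq_len(k), function(w) {
    x[((w - 1) * window_size + 1):(w * window_size)]
  })
}

#' Per-window spectral slopes for every session of a cohort
#'
#' The rolling-window ("evolutionary spectra") feature extraction: each
#' session is cleaned by compaction, segmented into non-overlapping windows,
#' and the wavelet spectral slope of each window is estimated. Windows whose
#' spectrum is degenerate (e.g. constant data) yield `NA` slopes.
#'
#' @param cohort Long cohort tibble.
#' @param window_size Window length (power of two, default 1024).
#' @param wavelet Wavelet name (default `"db6"`).
#' @param n_levels Detail levels per window (default 5).
#' @param estimator Energy estimator (see [energy_estimator()]).
#' @param detrend Per-window detrending, as in [estimate_hurst()].
#' @param level_range Regression levels; `NULL` = automatic ([hurst_levels()]).
#' @param max_missing_fraction Session rejection threshold.
#'
#' @return A tibble with one row per (participant, session, window):
#'   `participant_id`, `group`, `session`, `window`, `slope`, `hurst`.
#' @export
window_slopes <- function(cohort, window_size = 1024, wavelet = "db6",
                          n_levels = 5, estimator = "distance_variance",
                          detrend = c("bridge", "none"),
                          level_range = NULL,
                          max_missing_fraction = 0.8) {
  detrend <- match.arg(detrend)
  sessions <- clean_sessions(cohort, max_missing_fraction)
  sessions <- dplyr::filter(sessions, !.data$rejected)
  if (nrow(sessions) == 0) {
    abort("All sessions were rejected during cleaning.",
          class = "pw_data_error")
  }
  rows <- purrr::pmap(
    list(sessions$participant_id, sessions$group, sessions$session,
         sessions$values),
    function(id, grp, sess, values) {
      windows <- suppressWarnings(segment_windows(values, window_size))
      if (length(windows) == 0) return(NULL)
      slopes <- purrr::map_dbl(windows, function(w) {
        fit <- tryCatch(
          estimate_hurst(w, wavelet = wavelet, n_levels = n_levels,
                         estimator = estimator, detrend = detrend,
                         level_range = level_range),
          error = function(e) NULL
        )
        if (is.null(fit)) NA_real_ else fit$slope
      })
      tibble(participant_id = id, group = grp, session = sess,
             window = seq_along(slopes), slope = slopes,
             hurst = -(slopes + 1) / 2)
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("No windows could be extracted from any session.",
          class = "pw_data_error")
  }
  out
}

#' Session-averaged feature matrix
#'
#' Averages the per-window spectral slopes over a subject's sessions (the
#' average over the 8 sessions for each window position), producing one
#' feature row per subject. Window positions are aligned across sessions and
#' subjects by truncating to the cohort-wide minimum window count.
#'
#' @param slopes Output of [window_slopes()].
#'
#' @return A tibble of class `feature_matrix` with columns `participant_id`,
#'   `group` and `f_001` ... `f_k` (session-averaged slopes). The window size
#'   alignment count `k` is stored in attribute `n_windows`.
#' @export
feature_matrix <- function(slopes) {
  needed <- c("participant_id", "group", "session", "window", "slope")
  missing_cols <- setdiff(needed, names(slopes))
  if (length(missing_cols) > 0) {
    abort(paste0("`slopes` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pw_schema_error")
  }
  k <- slopes |>
    dplyr::group_by(.data$participant_id, .data$session) |>
    dplyr::summarise(k = max(.data$window), .groups = "drop") |>
    dplyr::pull(k) |>
    min()
  avg <- slopes |>
    dplyr::filter(.data$window <= k) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$window) |>
    dplyr::summarise(
      slope = if (all(is.na(.data$slope))) NA_real_
              else mean(.data$slope, na.rm = TRUE),
      .groups = "drop"
    )
  wide <- avg |>
    dplyr::mutate(feature = sprintf("f_%03d", .data$window)) |>
    dplyr::select(-"window") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "slope") |>
    dplyr::arrange(.data$group, .data$participant_id)
  structure(wide, class = c("feature_matrix", class(tibble())),
            n_windows = k)
}

feature_cols <- function(features) {
  grep("^f_\\d+$", names(features), value = TRUE)
}

#' Fisher criterion scores for each feature
#'
#' For each feature column, computes
#' `F = (mu_case - mu_control)^2 / (s2_case + s2_control)` from the group
#' sample means and variances over subjects. Features with zero pooled
#' variance get `F = 0` with a warning. The score is invariant to affine
#' rescaling of a feature applied to both groups.
#'
#' @param features A [feature_matrix()] (or any tibble with `group` and
#'   `f_*` columns; `group` must have exactly two levels, the
#'   lexicographically first is treated as "case" if named so, otherwise the
#'   two levels are used as-is — the score is symmetric in the two groups).
#'
#' @return A tibble with columns `feature`, `index` and `score`, ordered by
#'   feature index.
#' @export
fisher_scores <- function(features) {
  cols <- feature_cols(features)
  if (length(cols) == 0) {
    abort("No feature columns (f_*) found.", class = "pw_schema_error")
  }
  groups <- unique(features$group)
  if (length(groups) != 2) {
    abort("`features` must contain exactly two groups.",
          class = "pw_domain_error")
  }
  g1 <- features$group == groups[1]
  if (sum(g1) < 2 || sum(!g1) < 2) {
    abort("Each group needs at least 2 subjects for Fisher scores.",
          class = "pw_domain_error")
  }
  scores <- purrr::map_dbl(cols, function(cn) {
    x1 <- features[[cn]][g1]
    x2 <- features[[cn]][!g1]
    x1 <- x1[!is.na(x1)]
    x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) return(0)
    denom <- var(x1) + var(x2)
    if (denom == 0) {
      warn(sprintf("Feature %s has zero pooled variance; F set to 0.", cn))
      return(0)
    }
    (mean(x1) - mean(x2))^2 / denom
  })
  tibble(feature = cols, index = seq_along(cols), score = scores)
}

#' Select the top features by Fisher score
#'
#' Returns the indices of the `m` largest scores, in descending score order;
#' ties are broken in favour of the lower index.
#'
#' @param scores Output of [fisher_scores()] (or a bare numeric vector).
#' @param m Number of features to select (default 6).
#'
#' @return Integer vector of feature indices (1-based), length `m`.
#' @export
#'
#' @examples
#' select_features(c(0.1, 0.9, 0.5), m = 2) # c(2, 3)
select_features <- function(scores, m = 6) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  check_scalar_number(m, "m", lower = 1, integerish = TRUE)
  if (m > length(s)) {
    abort(sprintf("Cannot select %d features out of %d.", m, length(s)),
          class = "pw_domain_error")
  }
  order(-s, seq_along(s))[seq_len(m)]
}
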