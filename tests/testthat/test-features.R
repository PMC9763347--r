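test_that("cleaning compacts in order and rejects mostly-missing signals", {
  values <- as.numeric(1:100)
  missing <- rep(FALSE, 100)
  missing[sample(100, 30)] <- TRUE
  out <- clean_signal(values, missing)
  expect_length(out$values, 70)
  expect_identical(out$values, values[!missing]) # order preserved
  expect_false(out$rejected)

  mostly <- rep(TRUE, 100)
  mostly[1:15] <- FALSE # 85% missing
  expect_true(clean_signal(values, mostly)$rejected)
  # exactly 80% is kept ("more than 80%" is the rejection rule)
  at_80 <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 20)
  expect_false(clean_signal(values, at_80)$rejected)

  intact <- clean_signal(values, rep(FALSE, 100))
  expect_identical(intact$values, values)
})

test_that("segmentation tiles the signal prefix exactly", {
  expect_length(segment_windows(numeric(165000), 1024), 161)
  x <- rnorm(2048)
  w <- segment_windows(x, 1024)
  expect_length(w, 2)
  expect_identical(unlist(w), x)
  expect_warning(out <- segment_windows(rnorm(1000), 1024), "window")
  expect_length(out, 0)
  expect_error(segment_windows(x, 1000), class = "pw_domain_error")
  expect_error(segment_windows(x, 32), class = "pw_domain_error")
})

test_that("window slopes have full cardinality on clean sessions", {
  cohort <- small_cohort(2, session_length = 4096, sessions = 2,
                         missing_fraction = 0, seed = 42)
  slopes <- window_slopes(cohort, window_size = 1024)
  # 4 subjects x 2 sessions x 4 windows
  expect_equal(nrow(slopes), 4 * 2 * 4)
  expect_false(anyNA(slopes$slope))
  expect_equal(slopes$hurst, -(slopes$slope + 1) / 2)
})

test_that("constant sessions yield masked windows", {
  cohort <- tibble::tibble(
    participant_id = "p1", group = "case", session = 1L,
    sample = 0:2047, value = 5, missing = FALSE
  )
  slopes <- suppressWarnings(window_slopes(cohort, window_size = 1024))
  expect_true(all(is.na(slopes$slope)))
})

test_that("fBm window slopes cluster around -(2H + 1)", {
  cohort <- small_cohort(2, H_case = 0.9, H_control = 0.9,
                         session_length = 16384, sessions = 2,
                         missing_fraction = 0, seed = 42)
  slopes <- window_slopes(cohort, window_size = 1024)
  expect_lt(abs(mean(slopes$slope) - (-2.8)), 0.15)
})

test_that("session averaging is the column mean over unmasked entries", {
  slopes <- tibble::tibble(
    participant_id = "p1", group = "case",
    session = rep(1:2, each = 3), window = rep(1:3, 2),
    slope = c(-2, -2, -2, -4, -4, -4), hurst = NA_real_
  )
  fm <- feature_matrix(slopes)
  expect_equal(unname(unlist(fm[1, c("f_001", "f_002", "f_003")])),
               c(-3, -3, -3))

  # single session passes through unchanged
  fm1 <- feature_matrix(dplyr::filter(slopes, session == 1))
  expect_equal(unname(unlist(fm1[1, c("f_001", "f_002", "f_003")])),
               c(-2, -2, -2))

  # one masked cell: mean over the remaining session
  slopes$slope[2] <- NA
  fm2 <- feature_matrix(slopes)
  expect_equal(fm2$f_002, -4)
})

test_that("windows are aligned to the cohort-wide minimum count", {
  slopes <- tibble::tibble(
    participant_id = rep(c("a", "b"), c(4, 2)),
    group = rep(c("case", "control"), c(4, 2)),
    session = 1L,
    window = c(1:4, 1:2),
    slope = rnorm(6), hurst = NA_real_
  )
  fm <- feature_matrix(slopes)
  expect_equal(attr(fm, "n_windows"), 2)
  expect_equal(sort(pupilwave:::feature_cols(fm)), c("f_001", "f_002"))
})

test_that("Fisher scores match the closed-form criterion", {
  fm <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"),
    group = c("case", "case", "control", "control"),
    f_001 = c(2, 4, 0, 2),   # (3-1)^2 / (2+2) = 1
    f_002 = c(1, 2, 1, 2),   # identical distributions -> 0
    f_003 = c(20, 40, 0, 20) # column scaled by 10: F unchanged
  )
  sc <- fisher_scores(fm)
  expect_equal(sc$score[1], 1)
  expect_equal(sc$score[2], 0)
  expect_equal(sc$score[3], sc$score[1])
  # shifting a column in both groups leaves F unchanged
  fm$f_001 <- fm$f_001 + 100
  expect_equal(fisher_scores(fm)$score[1], 1)
  # constant feature: F = 0 with a warning
  fm$f_002 <- 3
  expect_warning(sc2 <- fisher_scores(fm), "zero pooled variance")
  expect_equal(sc2$score[2], 0)
})

test_that("feature selection returns the top-m indices with stable ties", {
  expect_equal(select_features(c(0.1, 0.9, 0.5), 2), c(2L, 3L))
  expect_equal(select_features(c(0.4, 0.4, 0.4), 2), c(1L, 2L))
  set.seed(42)
  for (r in 1:20) {
    s <- sample(round(runif(12), 2)) # ties likely
    m <- sample(1:12, 1)
    got <- select_features(s, m)
    oracle <- order(-s, seq_along(s))[seq_len(m)] # brute-force sort
    expect_identical(got, oracle)
    expect_true(all(s[got] >= max(s[-got], -Inf) | length(got) == 12))
  }
  expect_error(select_features(c(1, 2), 3), class = "pw_domain_error")
})

test_that("group slope means order by Hurst separation end to end", {
  cohort <- small_cohort(3, H_case = 0.7, H_control = 0.95,
                         session_length = 8192, sessions = 2, seed = 42)
  slopes <- window_slopes(cohort)
  means <- slopes |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(slope, na.rm = TRUE))
  # slope = -(2H + 1): lower H (cases) means slope closer to zero
  expect_gt(means$m[means$group == "case"],
            means$m[means$group == "control"])
})
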