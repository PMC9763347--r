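# Independent oracles used across test files. These deliberately avoid the
# package's own recursion/fast paths: the transform matrix is assembled
# explicitly from the filter taps, and summary statistics are computed by
# direct enumeration.

# One-level analysis matrix (low-pass rows stacked over high-pass rows) built
# directly from the filter taps as a downsampled circulant.
analysis_matrix_1 <- function(n, wavelet) {
  filt <- wavelet_filter(wavelet)
  L <- length(filt$h)
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (l in seq_len(L)) {
      col <- ((2 * (k - 1) + l - 1) %% n) + 1
      W[k, col] <- W[k, col] + filt$h[l]
      W[n / 2 + k, col] <- W[n / 2 + k, col] + filt$g[l]
    }
  }
  W
}

# Full multi-level orthogonal transform matrix: cascade of one-level analysis
# blocks acting on the running approximation part. Output coefficient order:
# smooth, then details coarse -> fine.
full_transform_matrix <- function(n, wavelet, n_levels) {
  W <- diag(n)
  m <- n
  for (lev in seq_len(n_levels)) {
    step <- diag(n)
    step[1:m, 1:m] <- analysis_matrix_1(m, wavelet)
    W <- step %*% W
    m <- m / 2
  }
  # rows currently: [approx_m, detail_m, detail_2m, ..., detail_{n/2}]
  W
}

# coefficients of a wavelet_decomposition in the matrix-product row order
decomposition_as_vector <- function(decomp) {
  c(decomp$smooth, unlist(unname(decomp$details)))
}

# brute-force Youden search by direct enumeration over candidate thresholds
youden_brute_force <- function(probabilities, labels) {
  y <- labels
  best <- list(threshold = NA_real_, gamma = -Inf)
  for (thr in sort(unique(probabilities))) {
    pred <- probabilities >= thr
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    gam <- (sens + spec - 1) / sqrt(2)
    if (gam > best$gamma + 1e-12) best <- list(threshold = thr, gamma = gam)
  }
  best
}

# small synthetic cohort used by several tests
small_cohort <- function(n_per_group = 3, H_case = 0.6, H_control = 0.95,
                         session_length = 4096, sessions = 2, seed = 42,
                         missing_fraction = 0.2) {
  simulate_cohort(cohort_spec(
    n_cases = n_per_group, n_controls = n_per_group,
    H_case = H_case, H_control = H_control,
    sessions_per_subject = sessions, session_length = session_length,
    missing_fraction = missing_fraction, blink_burst_length = 64,
    seed = seed
  ))
}
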