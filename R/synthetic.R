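#' Simulate standard Brownian motion
#'
#' Cumulative sum of iid standard Gaussian increments. The Hurst exponent of
#' this process is 0.5.
#'
#' @param n Number of samples (at least 2).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#'
#' @return Numeric vector of length `n`.
#' @export
#'
#' @examples
#' x <- simulate_brownian(1024, seed = 1)
simulate_brownian <- function(n, seed = NULL) {
  check_scalar_number(n, "n", lower = 2, integerish = TRUE)
  with_seed_(seed, cumsum(rnorm(n)))
}

#' Simulate fractional Gaussian noise (exact)
#'
#' Stationary increments of fractional Brownian motion, generated by circulant
#' embedding (Davies-Harte): the Toeplitz autocovariance of the fGn is
#' embedded in a circulant matrix whose eigenvalues are obtained by FFT, so
#' the sample has exactly the target law. Falls back to a Cholesky
#' factorization of the covariance for tiny samples or in the (rare) case of
#' a failed embedding.
#'
#' @param n Number of increments (at least 1).
#' @param H Hurst exponent in (0, 1).
#' @param seed Optional integer seed.
#' @param method `"circulant"` (default) or `"cholesky"`.
#'
#' @return Numeric vector of length `n` with `N(0, 1)` marginals and the fGn
#'   autocovariance `0.5 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})`.
#' @export
simulate_fgn <- function(n, H, seed = NULL,
                         method = c("circulant", "cholesky")) {
  method <- match.arg(method)
  check_scalar_number(n, "n", lower = 1, integerish = TRUE)
  if (!is.numeric(H) || length(H) != 1 || H <= 0 || H >= 1) {
    abort("`H` must be a single number in (0, 1).", class = "pw_domain_error")
  }
  if (n < 16 && method == "circulant") method <- "cholesky"
  with_seed_(seed, {
    if (method == "cholesky") fgn_cholesky(n, H) else fgn_circulant(n, H)
  })
}

fgn_acvf <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

fgn_circulant <- function(n, H) {
  gam <- fgn_acvf(0:n, H)
  row <- c(gam, rev(gam[2:n]))
  m <- 2L * n
  lam <- Re(fft(row))
  if (min(lam) < -1e-8 * max(lam)) {
    return(fgn_cholesky(n, H))
  }
  lam[lam < 0] <- 0
  U <- rnorm(m)
  V <- rnorm(m)
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1] / m) * U[1]
  w[n + 1] <- sqrt(lam[n + 1] / m) * U[n + 1]
  k <- 2:n
  w[k] <- sqrt(lam[k] / (2 * m)) * complex(real = U[k], imaginary = V[k])
  w[m + 2 - k] <- Conj(w[k])
  Re(fft(w))[seq_len(n)]
}

fgn_cholesky <- function(n, H) {
  Sigma <- outer(seq_len(n), seq_len(n),
                 function(i, j) fgn_acvf(i - j, H))
  R <- chol(Sigma)
  as.numeric(crossprod(R, rnorm(n)))
}

#' Simulate fractional Brownian motion (exact)
#'
#' Partial sums of [simulate_fgn()] increments; `X_t` has the fBm covariance
#' `0.5 * (s^{2H} + t^{2H} - |s - t|^{2H})`. At `H = 0.5` the law coincides
#' with [simulate_brownian()].
#'
#' @inheritParams simulate_fgn
#' @param n Number of samples (at least 2).
#'
#' @return Numeric vector of length `n`.
#' @export
#'
#' @examples
#' x <- simulate_fbm(2048, H = 0.8, seed = 3)
simulate_fbm <- function(n, H, seed = NULL,
                         method = c("circulant", "cholesky")) {
  check_scalar_number(n, "n", lower = 2, integerish = TRUE)
  cumsum(simulate_fgn(n, H, seed = seed, method = method))
}

#' Contaminate detail coefficients with additive Gaussian noise
#'
#' At each detail level, `min(n_per_level, level size)` distinct positions are
#' chosen uniformly at random and perturbed by additive `N(0, sd^2)` noise.
#' Smooth coefficients and unselected positions are untouched. Used to probe
#' the outlier resistance of spectral estimators.
#'
#' @param decomp A `wavelet_decomposition`.
#' @param n_per_level Number of coefficients to contaminate per level (levels
#'   with fewer coefficients are fully contaminated).
#' @param noise_sd Noise standard deviation. `NULL` (default) calibrates to
#'   the data: the empirical SD of the level's own coefficients
#'   (`noise_mode = "level"`) or of all detail coefficients pooled
#'   (`noise_mode = "global"`), times `noise_scale`.
#' @param noise_mode `"level"` or `"global"`; ignored when `noise_sd` is given.
#' @param noise_scale Multiplier applied to the empirical SD.
#' @param seed Optional integer seed.
#'
#' @return A new `wavelet_decomposition`.
#' @export
contaminate_decomposition <- function(decomp, n_per_level = 100,
                                      noise_sd = NULL,
                                      noise_mode = c("level", "global"),
                                      noise_scale = 1,
                                      seed = NULL) {
  validate_decomposition(decomp)
  noise_mode <- match.arg(noise_mode)
  check_scalar_number(n_per_level, "n_per_level", lower = 0,
                      integerish = TRUE)
  if (!is.null(noise_sd)) {
    check_scalar_number(noise_sd, "noise_sd", lower = 0)
  }
  check_scalar_number(noise_scale, "noise_scale", lower = 0)
  if (n_per_level == 0) return(decomp)
  global_sd <- sd(unlist(decomp$details))
  with_seed_(seed, {
    decomp$details <- purrr::map(decomp$details, function(d) {
      nc <- min(n_per_level, length(d))
      s <- if (!is.null(noise_sd)) {
        noise_sd
      } else {
        noise_scale * (if (noise_mode == "level") sd(d) else global_sd)
      }
      if (nc == 0 || s == 0) return(d)
      pos <- sample.int(length(d), nc)
      d[pos] <- d[pos] + rnorm(nc, 0, s)
      d
    })
    decomp
  })
}

#' Specification of a synthetic pupillometry-like cohort
#'
#' Describes a two-group cohort of multi-session recordings in which each
#' session is an exact fractional Brownian motion path at the group's Hurst
#' exponent, rescaled to a plausible pupil-diameter range, with missing
#' samples placed in contiguous blink-like bursts. Defaults mirror the
#' structure of a task-based pupillometry experiment: 28 cases and 22
#' controls, 8 sessions per subject of 165,000 samples at 1 kHz, with cases
#' showing less regular (lower `H`) dynamics than controls.
#'
#' @param n_cases,n_controls Subjects per group.
#' @param H_case,H_control Group Hurst exponents in (0, 1).
#' @param sessions_per_subject Sessions per subject.
#' @param session_length Samples per session.
#' @param missing_fraction Fraction of samples masked per session, in
#'   `[0, 0.8)` so signals survive the 80% cleaning rule.
#' @param blink_burst_length Length (samples) of each contiguous missing burst.
#' @param sampling_rate Sampling rate in Hz (metadata only).
#' @param seed Optional integer seed used by [simulate_cohort()].
#'
#' @return An object of class `cohort_spec`.
#' @export
#'
#' @examples
#' spec <- cohort_spec(n_cases = 2, n_controls = 2, session_length = 4096)
cohort_spec <- function(n_cases = 28, n_controls = 22,
                        H_case = 0.85, H_control = 0.95,
                        sessions_per_subject = 8,
                        session_length = 165000,
                        missing_fraction = 0.3,
                        blink_burst_length = 200,
                        sampling_rate = 1000,
                        seed = NULL) {
  check_scalar_number(n_cases, "n_cases", lower = 1, integerish = TRUE)
  check_scalar_number(n_controls, "n_controls", lower = 1, integerish = TRUE)
  for (h in c(H_case = H_case, H_control = H_control)) {
    if (!is.numeric(h) || h <= 0 || h >= 1) {
      abort("Hurst exponents must lie in (0, 1).", class = "pw_domain_error")
    }
  }
  check_scalar_number(sessions_per_subject, "sessions_per_subject",
                      lower = 1, integerish = TRUE)
  check_scalar_number(session_length, "session_length", lower = 16,
                      integerish = TRUE)
  check_scalar_number(missing_fraction, "missing_fraction", lower = 0,
                      upper = 0.8 - 1e-12)
  check_scalar_number(blink_burst_length, "blink_burst_length", lower = 1,
                      integerish = TRUE)
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         H_case = H_case, H_control = H_control,
         sessions_per_subject = sessions_per_subject,
         session_length = session_length,
         missing_fraction = missing_fraction,
         blink_burst_length = blink_burst_length,
         sampling_rate = sampling_rate,
         seed = seed),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_spec> %d cases (H = %.2f) + %d controls (H = %.2f), ",
           "%d sessions x %d samples, %.0f%% missing in bursts of %d\n"),
    x$n_cases, x$H_case, x$n_controls, x$H_control,
    x$sessions_per_subject, x$session_length,
    100 * x$missing_fraction, x$blink_burst_length
  ))
  invisible(x)
}

#' Simulate a synthetic two-group cohort
#'
#' Generates the long-format cohort table described by a [cohort_spec()]:
#' one row per sample with columns `participant_id`, `group`, `session`,
#' `sample` (0-based within session), `value` (NA where missing) and
#' `missing`. Fully reproducible from `spec$seed`.
#'
#' Each session is an independent fBm path at the group's Hurst exponent,
#' affinely rescaled to a resting pupil diameter of about 4 mm with ~0.3 mm
#' fluctuation (affine maps do not change spectral slopes). Missing samples
#' are placed as contiguous bursts of `blink_burst_length` samples on
#' non-overlapping slots, emulating blink artifacts.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A tibble in long cohort format.
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(cohort_spec(2, 2, session_length = 4096, seed = 1))
#' dplyr::count(cohort, participant_id, session)
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a `cohort_spec` object.", class = "pw_domain_error")
  }
  groups <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  ids <- c(sprintf("case%02d", seq_len(spec$n_cases)),
           sprintf("control%02d", seq_len(spec$n_controls)))
  n <- spec$session_length
  with_seed_(spec$seed, {
    rows <- purrr::map2(ids, groups, function(id, grp) {
      H <- if (grp == "case") spec$H_case else spec$H_control
      sess <- purrr::map(seq_len(spec$sessions_per_subject), function(s) {
        path <- simulate_fbm(n, H)
        value <- 4 + 0.3 * (path - mean(path)) / max(sd(path), 1e-12)
        miss <- blink_mask(n, spec$missing_fraction, spec$blink_burst_length)
        value[miss] <- NA_real_
        tibble(participant_id = id, group = grp, session = s,
               sample = seq_len(n) - 1L, value = value, missing = miss)
      })
      dplyr::bind_rows(sess)
    })
    dplyr::bind_rows(rows)
  })
}

# contiguous blink bursts on non-overlapping slots covering ~ the target
# fraction of the session
blink_mask <- function(n, missing_fraction, burst_length) {
  miss <- rep(FALSE, n)
  if (missing_fraction <= 0) return(miss)
  burst_length <- min(burst_length, n)
  n_slots <- n %/% burst_length
  n_bursts <- min(n_slots, round(missing_fraction * n / burst_length))
  if (n_bursts == 0) return(miss)
  slots <- sample.int(n_slots, n_bursts)
  for (s in slots) {
    i0 <- (s - 1L) * burst_length
    miss[(i0 + 1L):(i0 + burst_length)] <- TRUE
  }
  miss
}
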