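#' Wavelet spectrum of a decomposition
#'
#' The wavelet spectrum is the sequence of log2 level-wise energies
#' `S(j) = log2(energy(d_j))` of the detail coefficients, as a function of the
#' level `j`. For self-similar signals S(j) decays linearly with slope
#' `-(2H + 1)`, where `H` is the Hurst exponent. Energies are estimated either
#' by the classical sample variance or the distance variance (see
#' [level_energy()]).
#'
#' Levels with fewer than 2 coefficients or exactly zero energy are skipped
#' with a warning rather than mapped to `-Inf`.
#'
#' @param decomp A `wavelet_decomposition` with at least 3 detail levels.
#' @param estimator Energy estimator (see [energy_estimator()]).
#'
#' @return A tibble of class `wavelet_spectrum` with columns `level`,
#'   `n_coefficients`, `energy`, `log2_energy`, and attributes `estimator`,
#'   `wavelet`, `n_original`.
#' @export
#'
#' @examples
#' x <- simulate_brownian(1024, seed = 1)
#' sp <- wavelet_spectrum(dwt_forward(x, "db6", n_levels = 9))
#' sp
wavelet_spectrum <- function(decomp, estimator = "distance_variance") {
  validate_decomposition(decomp)
  est <- as_energy_estimator(estimator)
  if (length(decomp$details) < 3) {
    abort("At least 3 detail levels are required for a spectrum.",
          class = "pw_spectrum_error")
  }
  lev <- as.integer(names(decomp$details))
  rows <- purrr::map2(decomp$details, lev, function(d, j) {
    if (length(d) < 2) {
      warn(sprintf("Level %d skipped: fewer than 2 coefficients.", j))
      return(NULL)
    }
    en <- level_energy(d, est)
    if (en <= 0) {
      warn(sprintf("Level %d skipped: zero energy.", j))
      return(NULL)
    }
    tibble(level = j, n_coefficients = length(d), energy = en,
           log2_energy = log2(en))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) < 3) {
    abort("Fewer than 3 usable levels: the spectral slope would be unstable.",
          class = "pw_spectrum_error")
  }
  out <- dplyr::arrange(out, .data$level)
  structure(out,
            class = c("wavelet_spectrum", class(tibble())),
            estimator = est,
            wavelet = decomp$wavelet,
            n_original = decomp$n)
}

#' Spectral slope and Hurst exponent from a wavelet spectrum
#'
#' Fits an ordinary least-squares line to the pairs `(j, S(j))` over the
#' selected levels and converts the slope to a Hurst exponent via
#' `H = -(slope + 1) / 2`.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param level_range Optional inclusive `c(lo, hi)` restricting the levels
#'   used. Default: all levels present in the spectrum.
#' @param method `"ols"` (default) or `"theil-sen"` (robust pairwise-median
#'   slope, for sensitivity analysis).
#'
#' @return An object of class `slope_fit` with elements `slope`, `intercept`,
#'   `hurst`, `r_squared`, `levels_used`, `estimator`, `wavelet`.
#' @export
#'
#' @examples
#' x <- simulate_brownian(1024, seed = 1)
#' fit <- estimate_slope(wavelet_spectrum(dwt_forward(x, "db6", 9)))
#' glance(fit)
estimate_slope <- function(spectrum, level_range = NULL,
                           method = c("ols", "theil-sen")) {
  method <- match.arg(method)
  if (!inherits(spectrum, "wavelet_spectrum")) {
    abort("`spectrum` must be a `wavelet_spectrum` object.",
          class = "pw_domain_error")
  }
  keep <- rep(TRUE, nrow(spectrum))
  if (!is.null(level_range)) {
    keep <- spectrum$level >= level_range[1] & spectrum$level <= level_range[2]
  }
  j <- spectrum$level[keep]
  S <- spectrum$log2_energy[keep]
  if (length(j) < 3) {
    abort("Fewer than 3 levels in the selected range.",
          class = "pw_domain_error")
  }
  if (method == "ols") {
    fit <- stats::lm.fit(cbind(intercept = 1, level = j), S)
    slope <- unname(fit$coefficients["level"])
    intercept <- unname(fit$coefficients["intercept"])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((S - mean(S))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  } else {
    pairs <- utils::combn(length(j), 2)
    slopes <- (S[pairs[2, ]] - S[pairs[1, ]]) / (j[pairs[2, ]] - j[pairs[1, ]])
    slope <- median(slopes)
    intercept <- median(S - slope * j)
    pred <- intercept + slope * j
    ss_tot <- sum((S - mean(S))^2)
    r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum((S - pred)^2) / ss_tot)) else 1
  }
  new_slope_fit(slope, intercept, r2, j,
                estimator = attr(spectrum, "estimator"),
                wavelet = attr(spectrum, "wavelet"))
}

new_slope_fit <- function(slope, intercept, r_squared, levels_used,
                          estimator = NULL, wavelet = NULL) {
  structure(
    list(slope = slope, intercept = intercept,
         hurst = -(slope + 1) / 2,
         r_squared = r_squared, levels_used = levels_used,
         estimator = estimator, wavelet = wavelet),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> slope = %.4f, H = %.4f (R^2 = %.3f, levels %s)\n",
    x$slope, x$hurst, x$r_squared,
    paste(range(x$levels_used), collapse = "..")
  ))
  invisible(x)
}

#' @rdname estimate_slope
#' @param x A `slope_fit` object.
#' @param ... Unused.
#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname estimate_slope
#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, hurst = x$hurst,
         r_squared = x$r_squared,
         n_levels = length(x$levels_used),
         estimator = if (is.null(x$estimator)) NA_character_
                     else x$estimator$kind)
}

#' Default level selection for Hurst estimation
#'
#' The automatic policy used by [estimate_hurst()]: drop the finest detail
#' level (the finest octave of a discretely sampled process deviates from the
#' theoretical scaling line) and any level with fewer than `min_coefficients`
#' coefficients (their log-energies are strongly biased). If fewer than 3
#' levels would remain, all levels are used instead.
#'
#' @param levels Integer vector of available detail levels `j`.
#' @param min_coefficients Minimum `2^j` coefficients for a level to be kept.
#'
#' @return Inclusive `c(lo, hi)` range of levels to use.
#' @export
hurst_levels <- function(levels, min_coefficients = 8) {
  levels <- sort(unique(as.integer(levels)))
  keep <- levels[2^levels >= min_coefficients & levels < max(levels)]
  if (length(keep) < 3) keep <- levels
  range(keep)
}

#' Estimate the Hurst exponent of a signal
#'
#' Convenience composition: (optional bridge detrending) -> [dwt_forward()] ->
#' [wavelet_spectrum()] -> [estimate_slope()]. The signal is truncated to the
#' largest power of two at or below its length.
#'
#' Bridge detrending subtracts the line joining the first and last samples.
#' The periodized transform treats the signal as circular, and the wrap-around
#' jump of a random-walk-like path otherwise leaks large boundary
#' coefficients into every level; removing the bridge eliminates this without
#' touching the scaling behaviour (the wavelets used have vanishing moments
#' beyond the linear trend).
#'
#' @param x Numeric signal, length at least `2^(n_levels + 1)`.
#' @param wavelet Wavelet name.
#' @param n_levels Number of detail levels (default: maximum).
#' @param estimator Energy estimator (see [energy_estimator()]).
#' @param detrend `"bridge"` (default) or `"none"`.
#' @param level_range Levels used in the slope regression; `NULL` applies the
#'   automatic policy of [hurst_levels()].
#' @param method Regression method passed to [estimate_slope()].
#'
#' @return A `slope_fit` (see [estimate_slope()]).
#' @export
#'
#' @examples
#' estimate_hurst(simulate_brownian(4096, seed = 7))$hurst
estimate_hurst <- function(x, wavelet = "db6", n_levels = NULL,
                           estimator = "distance_variance",
                           detrend = c("bridge", "none"),
                           level_range = NULL,
                           method = c("ols", "theil-sen")) {
  detrend <- match.arg(detrend)
  n2 <- largest_pow2(length(x))
  if (n2 < 8) {
    abort("Signal too short for Hurst estimation.", class = "pw_domain_error")
  }
  x <- x[seq_len(n2)]
  if (detrend == "bridge") x <- bridge_detrend(x)
  decomp <- dwt_forward(x, wavelet, n_levels)
  sp <- wavelet_spectrum(decomp, estimator)
  if (is.null(level_range)) level_range <- hurst_levels(sp$level)
  estimate_slope(sp, level_range, method)
}
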