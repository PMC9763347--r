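#' Forward discrete wavelet transform (periodized Mallat pyramid)
#'
#' Decomposes a dyadic-length signal into a coarse smooth approximation and a
#' hierarchy of detail coefficient vectors using an orthonormal wavelet filter
#' bank with periodic boundary handling. With periodic boundaries the
#' transform is exactly orthogonal: detail level `j` holds exactly `2^j`
#' coefficients and total energy is conserved (Parseval).
#'
#' Level indexing: for a signal of length `2^J`, detail levels run from the
#' coarsest retained level `J0 = J - n_levels` up to the finest level `J - 1`
#' (which has `2^(J-1)` coefficients). For self-similar signals the log2 level
#' energies decay linearly in `j` with slope `-(2H + 1)`.
#'
#' @param x Numeric signal whose length is a power of two.
#' @param wavelet Wavelet name (see [wavelet_filter()]).
#' @param n_levels Number of detail levels to extract, up to `J` (a full
#'   decomposition with a single smooth coefficient). Defaults to `J - 1`.
#'   Equivalently the "decomposition level" L gives `J0 = J - L`.
#'
#' @return An object of class `wavelet_decomposition`: a list with
#'   * `smooth` — coarsest-level approximation coefficients (length `2^J0`),
#'   * `details` — named list of detail vectors, names `"5"`, `"6"`, ... are
#'     the level numbers `j`, ordered coarse to fine,
#'   * `wavelet`, `n`, `J`, `J0`.
#' @export
#'
#' @examples
#' d <- dwt_forward(c(1, 1, 1, 1), "haar", n_levels = 1)
#' d$smooth
#' dwt_inverse(d)
dwt_forward <- function(x, wavelet = "db6", n_levels = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be a numeric vector with finite values.",
          class = "pw_domain_error")
  }
  n <- length(x)
  if (n < 2 || !is_power_of_two(n)) {
    abort(paste0(
      "Signal length must be a power of two (got ", n, "). ",
      "Truncate to the largest power of two below the length, e.g. ",
      "`x[seq_len(2^floor(log2(length(x))))]`, or zero-pad before calling."
    ), class = "pw_domain_error")
  }
  J <- as.integer(round(log2(n)))
  if (is.null(n_levels)) n_levels <- J - 1L
  check_scalar_number(n_levels, "n_levels", lower = 1, upper = J,
                      integerish = TRUE)
  n_levels <- as.integer(n_levels)
  filt <- wavelet_filter(wavelet)

  a <- x
  details <- vector("list", n_levels)
  for (i in seq_len(n_levels)) {
    s <- pyramid_step(a, filt$h, filt$g)
    details[[i]] <- s$detail # i-th finest: level J - i
    a <- s$approx
  }
  details <- rev(details) # coarse -> fine
  names(details) <- as.character(seq.int(J - n_levels, J - 1L))

  structure(
    list(smooth = a, details = details, wavelet = wavelet,
         n = n, J = J, J0 = J - n_levels),
    class = "wavelet_decomposition"
  )
}

# one analysis step of the pyramid with periodic boundaries:
# out[k] = sum_l f[l] * a[(2(k-1) + l - 1) mod m + 1]
pyramid_step <- function(a, h, g) {
  m <- length(a)
  L <- length(h)
  lo <- numeric(m)
  hi <- numeric(m)
  idx0 <- seq_len(m) - 1L
  for (l in seq_len(L)) {
    sh <- a[((idx0 + (l - 1L)) %% m) + 1L]
    lo <- lo + h[l] * sh
    hi <- hi + g[l] * sh
  }
  keep <- seq(1L, m, by = 2L)
  list(approx = lo[keep], detail = hi[keep])
}

#' Inverse discrete wavelet transform
#'
#' Reconstructs the original signal from a [dwt_forward()] decomposition.
#' Because the transform is orthogonal, the inverse is the adjoint of the
#' analysis operator and the round trip is exact to floating-point precision.
#'
#' @param decomp A `wavelet_decomposition` object.
#'
#' @return Numeric vector of length `decomp$n`.
#' @export
dwt_inverse <- function(decomp) {
  validate_decomposition(decomp)
  filt <- wavelet_filter(decomp$wavelet)
  a <- decomp$smooth
  for (d in decomp$details) { # coarse -> fine
    a <- synthesis_step(a, d, filt$h, filt$g)
  }
  a
}

synthesis_step <- function(a, d, h, g) {
  m2 <- length(a)
  m <- 2L * m2
  L <- length(h)
  out <- numeric(m)
  k0 <- 2L * (seq_len(m2) - 1L)
  for (l in seq_len(L)) {
    idx <- ((k0 + (l - 1L)) %% m) + 1L
    out[idx] <- out[idx] + h[l] * a + g[l] * d
  }
  out
}

validate_decomposition <- function(decomp) {
  if (!inherits(decomp, "wavelet_decomposition")) {
    abort("Expected a `wavelet_decomposition` object.",
          class = "pw_domain_error")
  }
  lens <- vapply(decomp$details, length, integer(1))
  lev <- as.integer(names(decomp$details))
  if (any(lens != 2^lev) || length(decomp$smooth) != 2^decomp$J0 ||
      length(decomp$smooth) + sum(lens) != decomp$n) {
    abort("Inconsistent level sizes in the decomposition.",
          class = "pw_integrity_error")
  }
  invisible(decomp)
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf(
    "<wavelet_decomposition> %s, n = %d (J = %d), detail levels %d..%d\n",
    x$wavelet, x$n, x$J, x$J0, x$J - 1L
  ))
  invisible(x)
}

#' Tidy a wavelet decomposition into a long tibble
#'
#' @param x A `wavelet_decomposition` object.
#' @param ... Unused.
#'
#' @return A tibble with columns `type` ("smooth"/"detail"), `level`,
#'   `position` (1-based within level) and `coefficient`.
#' @method tidy wavelet_decomposition
#' @export
tidy.wavelet_decomposition <- function(x, ...) {
  det <- purrr::imap(x$details, function(d, lev) {
    tibble(type = "detail", level = as.integer(lev),
           position = seq_along(d), coefficient = d)
  })
  dplyr::bind_rows(
    tibble(type = "smooth", level = x$J0,
           position = seq_along(x$smooth), coefficient = x$smooth),
    dplyr::bind_rows(det)
  )
}
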