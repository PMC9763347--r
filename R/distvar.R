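#' Sample distance variance of a numeric vector
#'
#' Computes the squared sample distance variance
#' \deqn{\nu^2_n(x) = \frac{1}{n^2}\sum_{i,j} A_{ij}^2,}
#' where \eqn{a_{ij} = |x_i - x_j|} and \eqn{A_{ij}} is the double-centered
#' distance matrix (rows, columns and grand mean removed). The statistic is
#' translation invariant and scale equivariant
#' (\eqn{\nu^2(a x + b) = a^2 \nu^2(x)}), is zero iff all elements are equal,
#' and is an outlier-resistant measure of spread.
#'
#' Two algorithms are provided: a quadratic-time reference implementation that
#' materializes the double-centered matrix, and a fast sort-based evaluation of
#' the same statistic using order statistics and cumulative sums, which runs in
#' O(n log n) time and is the default. Both return identical values to within
#' floating-point round-off.
#'
#' @param x Numeric vector, length at least 2, finite values.
#' @param algorithm `"fast"` (sort-based, default) or `"naive"` (quadratic
#'   reference implementation).
#'
#' @return A single non-negative number.
#' @export
#'
#' @examples
#' distance_variance(c(0, 1)) # 0.25
#' distance_variance(rnorm(100)) - distance_variance(rnorm(100), "naive")
distance_variance <- function(x, algorithm = c("fast", "naive")) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector with at least 2 elements.",
          class = "pw_domain_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`x` must contain only finite values.", class = "pw_domain_error")
  }
  if (algorithm == "naive") dvar_naive(x) else dvar_fast(x)
}

# reference implementation: explicit pairwise-distance matrix, double
# centering, mean of squares
dvar_naive <- function(x) {
  a <- abs(outer(x, x, "-"))
  A <- sweep(a, 1, rowMeans(a))
  A <- sweep(A, 2, colMeans(a))
  A <- A + mean(a)
  mean(A^2)
}

# O(n log n) evaluation. With a_ij = |x_i - x_j| symmetric,
#   (1/n^2) sum A_ij^2 = S1/n^2 - (2/n^3) sum_i r_i^2 + (T/n^2)^2
# where r_i = sum_j a_ij (row sums), T = sum_ij a_ij and
# S1 = sum_ij (x_i - x_j)^2 = 2n sum x^2 - 2 (sum x)^2. Row sums of the
# distance matrix come from sorting x once and prefix sums.
dvar_fast <- function(x) {
  n <- length(x)
  xs <- sort(x)
  cs <- cumsum(xs)
  i <- seq_len(n)
  r <- (i * xs - cs) + ((cs[n] - cs) - (n - i) * xs)
  S1 <- 2 * n * sum(x^2) - 2 * sum(x)^2
  T <- sum(r)
  v <- (S1 / n^2) - (2 / n^3) * sum(r^2) + (T / n^2)^2
  max(v, 0)
}

#' Energy estimator specification
#'
#' Describes how the level-wise energy of wavelet coefficients is estimated
#' when computing a wavelet spectrum: the classical sample variance (mean
#' squared deviation from the level mean, denominator `n`) or the distance
#' variance (see [distance_variance()]).
#'
#' @param kind `"distance_variance"` (default) or `"variance"`.
#' @param algorithm For distance variance, `"fast"` or `"naive"`; ignored for
#'   the variance kind.
#'
#' @return An object of class `energy_estimator`.
#' @export
#'
#' @examples
#' energy_estimator("variance")
energy_estimator <- function(kind = c("distance_variance", "variance"),
                             algorithm = c("fast", "naive")) {
  kind <- match.arg(kind)
  algorithm <- match.arg(algorithm)
  structure(list(kind = kind, algorithm = algorithm),
            class = "energy_estimator")
}

as_energy_estimator <- function(estimator) {
  if (inherits(estimator, "energy_estimator")) return(estimator)
  if (is.character(estimator) && length(estimator) == 1) {
    kind <- switch(estimator,
      dvar = ,
      distance_variance = "distance_variance",
      var = ,
      variance = "variance",
      abort(paste0("Unknown estimator `", estimator, "`."),
            class = "pw_domain_error")
    )
    return(energy_estimator(kind))
  }
  abort("`estimator` must be a string or an `energy_estimator` object.",
        class = "pw_domain_error")
}

#' @export
print.energy_estimator <- function(x, ...) {
  cat("<energy_estimator>", x$kind,
      if (x$kind == "distance_variance") paste0("(", x$algorithm, ")"), "\n")
  invisible(x)
}

#' Level energy of a coefficient vector
#'
#' @param coeffs Numeric vector of wavelet coefficients (length >= 2).
#' @param estimator An [energy_estimator()] or a shorthand string
#'   (`"variance"`, `"distance_variance"`, `"dvar"`).
#'
#' @return A single non-negative number.
#' @export
#'
#' @examples
#' level_energy(c(1, -1), "variance")          # 1
#' level_energy(c(1, -1), "distance_variance") # 1
level_energy <- function(coeffs, estimator = "distance_variance") {
  est <- as_energy_estimator(estimator)
  if (!is.numeric(coeffs) || length(coeffs) < 2) {
    abort("`coeffs` must have at least 2 elements.", class = "pw_domain_error")
  }
  if (est$kind == "variance") {
    mean((coeffs - mean(coeffs))^2)
  } else {
    distance_variance(coeffs, est$algorithm)
  }
}
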