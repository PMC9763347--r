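# internal helpers shared across modules

# run `code` under a fixed RNG state without disturbing the caller's stream;
# seed = NULL means "use the current stream"
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "pw_domain_error")
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "pw_domain_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper),
          class = "pw_domain_error")
  }
  invisible(x)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L
}

# largest power of two <= n (0 if n < 1)
largest_pow2 <- function(n) {
  if (n < 1) return(0L)
  2L^floor(log2(n))
}

# subtract the line joining the first and last sample ("bridge" detrending).
# Removes the wrap-around discontinuity a periodized transform would see.
bridge_detrend <- function(x) {
  n <- length(x)
  if (n < 2) return(x - x[1])
  x - (x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1))
}

check_cohort_columns <- function(data, call_name) {
  required <- c("participant_id", "group", "session", "sample", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: required column(s) missing: %s", call_name,
                  paste(missing_cols, collapse = ", ")),
          class = "pw_schema_error")
  }
  invisible(data)
}
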