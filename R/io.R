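#' Read a long-format cohort table
#'
#' Reads a CSV/TSV file with one sample per row and the required header
#' `participant_id, group, session, sample, value`. Values that fail numeric
#' parsing (e.g. empty fields or `"NaN"`) and values equal to an explicit
#' `missing_code` sentinel are flagged as missing. Rows are ordered by
#' participant, session and sample index; no rows are dropped, and duplicate
#' `(participant, session, sample)` keys raise an error.
#'
#' @param path Path to a delimited text file. The delimiter is inferred from
#'   the extension (`.tsv`/`.tab` -> tab, otherwise comma) unless `delim` is
#'   given.
#' @param missing_code Optional sentinel value (e.g. `0` or `-1`, as in some
#'   eye-tracker exports) additionally treated as missing.
#' @param delim Optional explicit field delimiter.
#'
#' @return A tibble with columns `participant_id` (character), `group`
#'   (character), `session` (integer), `sample` (integer), `value` (double,
#'   `NA` where missing) and `missing` (logical).
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(cohort_spec(1, 1, session_length = 256, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_cohort(cohort, f)
#' identical_cols <- all.equal(read_cohort(f)$value, cohort$value)
read_cohort <- function(path, missing_code = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "pw_io_error")
  }
  delim <- delim %||%
    (if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ",")
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  check_cohort_columns(stats::setNames(as.list(header), header),
                       "read_cohort")
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      session = readr::col_integer(),
      sample = readr::col_integer(),
      value = readr::col_character()
    ),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  check_cohort_columns(raw, "read_cohort")
  value <- suppressWarnings(as.numeric(raw$value))
  value[is.nan(value)] <- NA_real_
  missing <- is.na(value) | raw$value %in% c("", "NA", "NaN")
  if (!is.null(missing_code)) {
    missing <- missing |
      (!is.na(value) & value == as.numeric(missing_code)) |
      raw$value == as.character(missing_code)
  }
  value[missing] <- NA_real_
  out <- tibble(
    participant_id = raw$participant_id,
    group = raw$group,
    session = raw$session,
    sample = raw$sample,
    value = value,
    missing = missing
  )
  dup <- duplicated(out[c("participant_id", "session", "sample")])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    abort(sprintf(
      "Duplicate (participant, session, sample) key: (%s, %d, %d).",
      d$participant_id, d$session, d$sample
    ), class = "pw_integrity_error")
  }
  dplyr::arrange(out, .data$participant_id, .data$session, .data$sample)
}

#' Write a cohort table in long format
#'
#' The inverse of [read_cohort()]: one sample per row, missing samples
#' written as empty fields (or as `missing_code` if given). The written file
#' round-trips losslessly through [read_cohort()] up to floating-point
#' formatting precision.
#'
#' @param cohort A data frame with columns `participant_id`, `group`,
#'   `session`, `sample`, `value` (and optionally `missing`; if absent,
#'   `NA` values are taken as missing).
#' @param path Output path; delimiter inferred from the extension as in
#'   [read_cohort()].
#' @param missing_code String written for missing values (default: empty
#'   field).
#' @param delim Optional explicit delimiter.
#'
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, missing_code = "", delim = NULL) {
  check_cohort_columns(cohort, "write_cohort")
  missing <- if ("missing" %in% names(cohort)) cohort$missing
             else is.na(cohort$value)
  value_chr <- format_double(cohort$value)
  value_chr[missing] <- missing_code
  out <- data.frame(
    participant_id = cohort$participant_id,
    group = cohort$group,
    session = cohort$session,
    sample = cohort$sample,
    value = value_chr,
    stringsAsFactors = FALSE
  )
  delim <- delim %||%
    (if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ",")
  tryCatch(
    readr::write_delim(out, path, delim = delim, na = "", progress = FALSE),
    error = function(e) {
      abort(paste0("Cannot write to ", path, ": ", conditionMessage(e)),
            class = "pw_io_error")
    }
  )
  invisible(path)
}

format_double <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.15g", v)
  }, character(1))
  out
}
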