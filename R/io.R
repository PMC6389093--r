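# Readers and writers for referral tables: delimited text (CSV, RFC 4180)
# and a structured-record JSON format. Round trips are lossless, including
# missingness markers (empty CSV cell / JSON null — never 0).

#' Write a referral cohort to disk
#'
#' @param cohort a [referral_cohort()].
#' @param path output file path.
#' @param format `"csv"` (header row, RFC 4180 quoting; missing values as
#'   empty cells) or `"json"` (structured records; cohort label and filter
#'   log carried in the header object).
#' @return `path`, invisibly.
#' @export
write_referrals <- function(cohort, path, format = c("csv", "json")) {
  stopifnot(inherits(cohort, "referral_cohort"))
  format <- match.arg(format)
  df <- cohort$referrals
  for (col in c("onset_datetime", "referral_datetime", "arrival_datetime")) {
    df[[col]] <- format_datetime(df[[col]])
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    obj <- list(label = cohort$label,
                filter_log = as.list(cohort$filter_log),
                referrals = df)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null",
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a referral cohort from disk
#'
#' @param path input file.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @param label cohort tag for CSV files lacking a uniform `cohort` column;
#'   by default the (single) value of that column is used.
#' @return a [referral_cohort()].
#' @export
read_referrals <- function(path, format = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"),
                          na.strings = "")
    check_mandatory_columns(df, path)
    df <- parse_referral_rows(df, path)
    filter_log <- integer(0)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$referrals)) {
      stop(sprintf("%s: JSON referral file lacks a 'referrals' element", path),
           call. = FALSE)
    }
    df <- as.data.frame(obj$referrals, stringsAsFactors = FALSE)
    df$id <- as.character(df$id)
    check_mandatory_columns(df, path)
    df <- parse_referral_rows(df, path)
    label <- label %||% obj$label
    filter_log <- unlist(obj$filter_log) %||% integer(0)
  }
  label <- label %||% unique(df$cohort)
  if (length(label) != 1L) {
    stop(sprintf("%s: mixed cohort tags in one file; pass `label` explicitly",
                 path), call. = FALSE)
  }
  referral_cohort(df, label, filter_log = filter_log)
}

check_mandatory_columns <- function(df, path) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Field-level parsing with line-number-bearing error messages (line 1 is the
# header, so data row i is file line i + 1).
parse_referral_rows <- function(df, path) {
  parse_col <- function(col, fn) {
    tryCatch(fn(df[[col]]), error = function(e) {
      vals <- suppressWarnings(fn_quiet(df[[col]], fn))
      bad <- which(!is.na(df[[col]]) & is.na(vals))
      stop(sprintf("%s: malformed '%s' at line(s) %s", path, col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    })
  }
  fn_quiet <- function(x, fn) tryCatch(fn(x), error = function(e) rep(NA, length(x)))
  for (col in c("onset_datetime", "referral_datetime", "arrival_datetime")) {
    if (col %in% names(df)) df[[col]] <- parse_col(col, parse_datetime)
  }
  num_cols <- intersect(c("age_years", "systolic_mmHg", "diastolic_mmHg",
                          "duration_minutes"), names(df))
  for (col in num_cols) {
    v <- df[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric '%s' at line(s) %s", path, col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df
}
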