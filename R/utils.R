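# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Diagnosis and cohort enumerations used throughout the package.
DIAGNOSES <- c("TIA_MINOR_STROKE", "MIMIC", "OTHER", "UNKNOWN")
COHORTS <- c("PRE_QUEUE", "POST_QUEUE")
STRATA <- c("LOW", "MODERATE", "HIGH")

# All timestamps are timezone-naive local clinic time; we pin them to UTC so
# arithmetic never crosses DST boundaries.
TZ <- "UTC"

#' Run code with a temporary RNG state
#'
#' Seeds the session RNG, runs `expr`, and restores the previous RNG state so
#' that seeded package functions do not disturb the caller's random stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named RNG sub-stream seed from a master seed
#'
#' All randomness in an experiment flows from a single master seed; each stage
#' draws from its own deterministic sub-stream so adding a stage never
#' perturbs the draws of another.
#'
#' @param seed master integer seed.
#' @param name character name of the sub-stream.
#' @return an integer in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Parse ISO-8601-ish datetime strings ("2014-11-03 09:00:00" or with "T").
parse_datetime <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- TZ
    return(x)
  }
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  y <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(y, tz = TZ,
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable datetime value(s) at position(s) %s: %s",
                 paste(bad, collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

format_datetime <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = TZ)
  out[is.na(x)] <- NA_character_
  out
}

# is business day (Mon=1 .. Sun=7)
weekday_index <- function(date) as.integer(format(as.Date(date), "%u"))

is_business_day <- function(date, business_days = 1:5) {
  weekday_index(date) %in% business_days
}

next_business_day <- function(date, business_days = 1:5) {
  d <- as.Date(date) + 1L
  while (!is_business_day(d, business_days)) d <- d + 1L
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
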