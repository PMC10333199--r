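# Internal time helpers. All timestamps are POSIXct in UTC; files carry
# ISO-8601 strings. No local-time arithmetic anywhere.

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as_utc(x))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  blank <- is.na(x) | !nzchar(trimws(x))
  x2 <- sub("Z$", "", sub("T", " ", x[!blank]))
  fmt <- ifelse(grepl(":", x2), "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  parsed <- as.POSIXct(x2, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  dateonly <- is.na(parsed) & fmt == "%Y-%m-%d"
  parsed[dateonly] <- as.POSIXct(x2[dateonly], tz = "UTC", format = "%Y-%m-%d")
  out[!blank] <- parsed
  out
}

as_utc <- function(x) {
  attr(x, "tzone") <- "UTC"
  x
}

format_utc <- function(x) {
  # millisecond precision: detection times carry sub-second structure
  whole <- abs(as.numeric(x) - round(as.numeric(x))) < 5e-4
  out <- character(length(x))
  out[whole & !is.na(x)] <- format(x[whole & !is.na(x)],
                                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[!whole & !is.na(x)] <- format(x[!whole & !is.na(x)],
                                    "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  out[is.na(x)] <- ""
  out
}

utc_date <- function(x) as.Date(x, tz = "UTC")

# month-day string -> Date in the year of `ref`
season_end_date <- function(mmdd, ref) {
  as.Date(paste0(format(utc_date(ref), "%Y"), "-", mmdd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}
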