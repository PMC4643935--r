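#' Temperature series for one probe
#'
#' Lightweight container for the timestamped water-temperature records of a
#' single logger, with per-day quality-control flags.
#'
#' @param probe_id character scalar.
#' @param time `POSIXct` vector, strictly increasing.
#' @param temp_c numeric vector of water temperatures (degC), finite.
#' @param flags data frame with columns `date` (`Date`) and `flag`
#'   (character, e.g. `"out_of_water"`), or `NULL`.
#' @return an object of class `temp_series`.
#' @export
temp_series <- function(probe_id, time, temp_c, flags = NULL) {
  stopifnot(is.character(probe_id), length(probe_id) == 1)
  if (!inherits(time, "POSIXct")) stop("'time' must be POSIXct", call. = FALSE)
  if (length(time) != length(temp_c)) {
    stop("'time' and 'temp_c' must have the same length", call. = FALSE)
  }
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(temp_c))) stop("temperatures must be finite", call. = FALSE)
  if (is.null(flags)) {
    flags <- data.frame(date = as.Date(character()), flag = character())
  }
  structure(list(probe_id = probe_id, time = time, temp_c = as.numeric(temp_c),
                 flags = flags),
            class = "temp_series")
}

#' @export
print.temp_series <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<temp_series> probe %s: %d records", x$probe_id, n))
  if (n > 0) {
    cat(sprintf(" (%s .. %s), %.1f-%.1f degC",
                format(min(x$time)), format(max(x$time)),
                min(x$temp_c), max(x$temp_c)))
  }
  cat("\n")
  if (nrow(x$flags) > 0) {
    cat(sprintf("  flagged days: %d (%s)\n", nrow(x$flags),
                paste(unique(x$flags$flag), collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.temp_series <- function(x) length(x$time)

# Data frame view of a series (one row per record).
series_df <- function(series) {
  data.frame(probe_id = series$probe_id, timestamp = series$time,
             temp_c = series$temp_c)
}

series_dates <- function(series) unique(clock_date(series$time))
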