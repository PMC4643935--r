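# Reading logger files and quality control.

# ISO-8601-ish timestamp parser returning NA (not an error) for
# unparseable entries, so callers can name the offending line.
parse_iso_times <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read a single logger file
#'
#' Expects delimited text with header `probe_id,timestamp,temp_c` and
#' ISO-8601 timestamps. Records are ordered and de-duplicated: duplicate
#' timestamps keep the first occurrence (with a warning), non-monotone
#' timestamps are sorted (with a warning), and an unparseable timestamp or
#' temperature is an error naming the offending line.
#'
#' @param path path to the file; must contain a single probe.
#' @return a [temp_series()].
#' @export
read_logger <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- read.csv(path, colClasses = "character")
  needed <- c("probe_id", "timestamp", "temp_c")
  if (!all(needed %in% names(raw))) {
    stop(sprintf("missing columns in %s: %s", path,
                 paste(setdiff(needed, names(raw)), collapse = ", ")),
         call. = FALSE)
  }
  ids <- unique(raw$probe_id)
  if (length(ids) != 1) {
    stop(sprintf("%s contains %d probe ids; expected one", path, length(ids)),
         call. = FALSE)
  }
  time <- parse_iso_times(raw$timestamp)
  if (anyNA(time)) {
    stop(sprintf("unparseable timestamp at line %d of %s",
                 which(is.na(time))[1] + 1L, path), call. = FALSE)
  }
  suppressWarnings(temp <- as.numeric(raw$temp_c))
  if (anyNA(temp)) {
    stop(sprintf("unparseable temperature at line %d of %s",
                 which(is.na(temp))[1] + 1L, path), call. = FALSE)
  }
  if (is.unsorted(as.numeric(time))) {
    warning(sprintf("timestamps in %s are not monotone; sorting", path))
    ord <- order(time)
    time <- time[ord]
    temp <- temp[ord]
  }
  dup <- duplicated(time)
  if (any(dup)) {
    warning(sprintf("%d duplicated timestamp(s) in %s; keeping first",
                    sum(dup), path))
    time <- time[!dup]
    temp <- temp[!dup]
  }
  temp_series(ids, time, temp)
}

#' Remove whole days flagged as out of water
#'
#' Removal is whole-day atomic: every record of a flagged calendar day is
#' dropped, and no partial days remain. Idempotent.
#'
#' @param series a [temp_series()].
#' @param flags `Date` vector of days to drop, or `NULL` to use the series'
#'   own `out_of_water` flags.
#' @return the filtered [temp_series()]; the number of probe-days removed is
#'   attached as attribute `days_removed`.
#' @export
drop_out_of_water_days <- function(series, flags = NULL) {
  if (is.null(flags)) {
    flags <- series$flags$date[series$flags$flag == "out_of_water"]
  }
  flags <- as.Date(flags)
  dates <- clock_date(series$time)
  keep <- !(dates %in% flags)
  removed <- length(unique(dates[!keep]))
  out <- temp_series(series$probe_id, series$time[keep], series$temp_c[keep],
                     series$flags)
  attr(out, "days_removed") <- removed
  out
}

#' Restrict a series to the summer analysis window
#'
#' Keeps records whose week-of-year lies in `window` (inclusive) and whose
#' year is in `years`. An empty result is a warning, not an error.
#'
#' @param series a [temp_series()].
#' @param window length-2 integer vector `(first_week, last_week)`.
#' @param years integer vector of years to keep, or `NULL` for all.
#' @param convention week-numbering convention, see [week_of_year()].
#' @return the filtered [temp_series()].
#' @export
select_summer_window <- function(series, window = c(24, 31), years = NULL,
                                 convention = c("iso", "ordinal")) {
  convention <- match.arg(convention)
  if (length(window) != 2 || window[1] > window[2] ||
      any(window < 1 | window > 53)) {
    stop("'window' must be (first_week, last_week) within 1..53", call. = FALSE)
  }
  wk <- week_of_year(series$time, convention)
  keep <- wk >= window[1] & wk <= window[2]
  if (!is.null(years)) {
    yr <- as.integer(strftime(series$time, "%Y"))
    keep <- keep & yr %in% years
  }
  if (!any(keep)) {
    warning(sprintf("no records of probe %s fall in the window",
                    series$probe_id))
  }
  temp_series(series$probe_id, series$time[keep], series$temp_c[keep],
              series$flags)
}

# Optional heuristic flagger (OFF by default in the pipeline): days whose
# range exceeds `threshold` degC are suspicious for air exposure.
#' Flag days with an implausibly large diel range
#'
#' Heuristic detector for probes that were out of the water; disabled by
#' default in the pipeline, which relies on explicit flags.
#'
#' @param series a [temp_series()].
#' @param threshold daily range (degC) above which a day is flagged.
#' @return `Date` vector of suspicious days.
#' @export
flag_out_of_water <- function(series, threshold = 15) {
  dates <- clock_date(series$time)
  rng <- tapply(series$temp_c, dates, function(v) diff(range(v)))
  as.Date(names(rng)[rng > threshold])
}

#' Quality control for a whole study
#'
#' Applies [drop_out_of_water_days()] and [select_summer_window()] to every
#' series of a study.
#'
#' @param study a `therm_study` (see [build_study()]) or a list with
#'   `probes` and `series`.
#' @param window,years,convention passed to [select_summer_window()];
#'   `NULL` defaults to the study's own window and years.
#' @return the study with QC'd series; a per-probe QC table is attached as
#'   attribute `qc_table`.
#' @export
qc_study <- function(study, window = NULL, years = NULL,
                     convention = "iso") {
  window <- window %||% study$window %||% c(24, 31)
  years <- years %||% study$years
  res <- lapply(study$series, function(s) {
    n0 <- length(s)
    s1 <- drop_out_of_water_days(s)
    removed <- attr(s1, "days_removed")
    s2 <- suppressWarnings(
      select_summer_window(s1, window, years, convention))
    list(series = s2,
         qc = data.frame(probe_id = s$probe_id, records_in = n0,
                         days_removed = removed,
                         records_out = length(s2)))
  })
  out <- study
  out$series <- lapply(res, `[[`, "series")
  out$window <- window
  out$years <- years
  attr(out, "qc_table") <- do.call(rbind, lapply(res, `[[`, "qc")) |>
    (\(d) {rownames(d) <- NULL; d})()
  out
}
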