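# Delimited-text interchange formats: probes.csv, willows.csv, and logger
# files (header probe_id,timestamp,temp_c with ISO-8601 timestamps).

#' Write a study to delimited text files
#'
#' Writes `probes.csv` with the metadata columns and the logger records
#' either as one long `loggers.csv` (default) or one file per probe under
#' `loggers/`. Flagged days are written to `flags.csv`.
#'
#' @param study a `therm_study`.
#' @param dir output directory (created if missing).
#' @param long single long file (`TRUE`) or one file per probe.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, long = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$probes, file.path(dir, "probes.csv"), row.names = FALSE)
  fmt <- function(s) {
    data.frame(probe_id = s$probe_id,
               timestamp = strftime(s$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               temp_c = sprintf("%.17g", s$temp_c))
  }
  if (long) {
    recs <- do.call(rbind, lapply(study$series, fmt))
    write.csv(recs, file.path(dir, "loggers.csv"), row.names = FALSE)
  } else {
    dir.create(file.path(dir, "loggers"), showWarnings = FALSE)
    for (s in study$series) {
      write.csv(fmt(s), file.path(dir, "loggers", paste0(s$probe_id, ".csv")),
                row.names = FALSE)
    }
  }
  flags <- do.call(rbind, lapply(study$series, function(s) {
    if (nrow(s$flags) == 0) return(NULL)
    data.frame(probe_id = s$probe_id, date = format(s$flags$date),
               flag = s$flags$flag)
  }))
  if (!is.null(flags)) {
    write.csv(flags, file.path(dir, "flags.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study from delimited text files
#'
#' Counterpart of [write_study()]: reads `probes.csv`, the logger records
#' (`loggers.csv` or `loggers/*.csv`), and optional `flags.csv`.
#'
#' @param dir directory holding the files.
#' @param window,years study window recorded on the returned object.
#' @return a `therm_study`.
#' @export
read_study <- function(dir, window = c(24, 31), years = NULL) {
  probes <- read.csv(file.path(dir, "probes.csv"))
  long_path <- file.path(dir, "loggers.csv")
  series <- list()
  if (file.exists(long_path)) {
    raw <- read.csv(long_path, colClasses = "character")
    time <- parse_iso_times(raw$timestamp)
    if (anyNA(time)) {
      stop(sprintf("unparseable timestamp at line %d of %s",
                   which(is.na(time))[1] + 1L, long_path), call. = FALSE)
    }
    suppressWarnings(temp <- as.numeric(raw$temp_c))
    if (anyNA(temp)) {
      stop(sprintf("unparseable temperature at line %d of %s",
                   which(is.na(temp))[1] + 1L, long_path), call. = FALSE)
    }
    for (pid in unique(raw$probe_id)) {
      idx <- which(raw$probe_id == pid)
      ord <- idx[order(time[idx])]
      ord <- ord[!duplicated(time[ord])]
      series[[pid]] <- temp_series(pid, time[ord], temp[ord])
    }
  } else {
    files <- list.files(file.path(dir, "loggers"), full.names = TRUE,
                        pattern = "\\.csv$")
    for (f in files) {
      s <- read_logger(f)
      series[[s$probe_id]] <- s
    }
  }
  fpath <- file.path(dir, "flags.csv")
  if (file.exists(fpath)) {
    flags <- read.csv(fpath)
    for (pid in unique(flags$probe_id)) {
      if (!pid %in% names(series)) next
      fl <- flags[flags$probe_id == pid, c("date", "flag")]
      fl$date <- as.Date(fl$date)
      series[[pid]]$flags <- fl
    }
  }
  missing <- setdiff(names(series), probes$probe_id)
  if (length(missing)) {
    stop(sprintf("series without metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(years)) {
    years <- sort(unique(unlist(lapply(series, function(s) {
      as.integer(unique(strftime(s$time, "%Y")))
    }))))
  }
  structure(list(probes = probes, series = series, window = window,
                 years = years),
            class = "therm_study")
}
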