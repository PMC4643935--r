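# Thermal metric hierarchy: daily summaries -> 7-day moving medians ->
# season maxima. The weekly metrics are medians, not means, so single
# aberrant days do not propagate.

#' Daily temperature summaries for one probe
#'
#' One row per calendar day with the daily minimum (`DminT`), arithmetic
#' mean (`DavgT`), and maximum (`DmaxT`). A day is complete when it holds at
#' least `completeness_frac` of the records expected from the sampling
#' interval; incomplete days are kept but marked, and excluded by
#' [weekly_moving_median()].
#'
#' @param series a QC'd [temp_series()].
#' @param completeness_frac minimum fraction of expected records; set to 0
#'   to disable the completeness check.
#' @param sampling_interval minutes between records; inferred from the
#'   series when `NULL`.
#' @return data frame with columns `probe_id`, `date`, `DminT`, `DavgT`,
#'   `DmaxT`, `n_records`, `complete`.
#' @export
daily_summaries <- function(series, completeness_frac = 0.75,
                            sampling_interval = NULL) {
  if (length(series) == 0) {
    return(data.frame(probe_id = character(), date = as.Date(character()),
                      DminT = numeric(), DavgT = numeric(), DmaxT = numeric(),
                      n_records = integer(), complete = logical()))
  }
  if (is.null(sampling_interval)) {
    sampling_interval <- if (length(series) > 1) {
      median(diff(as.numeric(series$time))) / 60
    } else 30
  }
  expected <- 1440 / sampling_interval
  dates <- clock_date(series$time)
  f <- factor(dates)
  out <- data.frame(
    probe_id = series$probe_id,
    date = as.Date(levels(f)),
    DminT = as.numeric(tapply(series$temp_c, f, min)),
    DavgT = as.numeric(tapply(series$temp_c, f, mean)),
    DmaxT = as.numeric(tapply(series$temp_c, f, max)),
    n_records = as.integer(tapply(series$temp_c, f, length))
  )
  out$complete <- out$n_records >= completeness_frac * expected
  rownames(out) <- NULL
  out
}

#' Seven-day moving medians of the daily metrics
#'
#' For every day with at least `min_days` complete days in its window, the
#' weekly metrics `WminT`, `WavgT`, `WmaxT` are the medians of the daily
#' `DminT`, `DavgT`, `DmaxT` in that window. Windows are calendar-day based
#' (gaps count as missing days) and centred by default (day -3..+3);
#' a trailing alignment (day -6..0) is available.
#'
#' @param daily a data frame from [daily_summaries()] (one or more probes).
#' @param window_days window width in days (odd for centred alignment).
#' @param min_days minimum number of complete days in the window.
#' @param align `"center"` or `"trailing"`.
#' @return data frame with columns `probe_id`, `date`, `WminT`, `WavgT`,
#'   `WmaxT`, `n_days`.
#' @export
weekly_moving_median <- function(daily, window_days = 7, min_days = 4,
                                 align = c("center", "trailing")) {
  align <- match.arg(align)
  if ("complete" %in% names(daily)) {
    daily <- daily[daily$complete, , drop = FALSE]
  }
  res <- lapply(split(daily, daily$probe_id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    dn <- as.numeric(d$date)
    if (align == "center") {
      h <- (window_days - 1) / 2
      lo <- dn - h; hi <- dn + h
    } else {
      lo <- dn - (window_days - 1); hi <- dn
    }
    n <- length(dn)
    wmin <- wavg <- wmax <- rep(NA_real_, n)
    ndays <- integer(n)
    # dn is sorted: track the window by two moving pointers
    a <- 1L; b <- 0L
    for (i in seq_len(n)) {
      while (a <= n && dn[a] < lo[i]) a <- a + 1L
      if (b < a - 1L) b <- a - 1L
      while (b < n && dn[b + 1L] <= hi[i]) b <- b + 1L
      k <- b - a + 1L
      ndays[i] <- k
      if (k >= min_days) {
        idx <- a:b
        wmin[i] <- median(d$DminT[idx])
        wavg[i] <- median(d$DavgT[idx])
        wmax[i] <- median(d$DmaxT[idx])
      }
    }
    keep <- ndays >= min_days
    if (!any(keep)) return(NULL)
    data.frame(probe_id = d$probe_id[1], date = d$date[keep],
               WminT = wmin[keep], WavgT = wavg[keep], WmaxT = wmax[keep],
               n_days = ndays[keep])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(probe_id = character(), date = as.Date(character()),
                      WminT = numeric(), WavgT = numeric(), WmaxT = numeric(),
                      n_days = integer())
  }
  rownames(out) <- NULL
  out
}

#' Season maxima of the weekly metrics
#'
#' `MWavgT` and `MWmaxT` are the maxima of the weekly average and weekly
#' maximum series -- the average and maximum temperatures of the warmest
#' consecutive seven days. With several years of data, `by = "overall"`
#' (default) returns the study-duration maxima; `by = "per_year"` returns
#' one row per probe and year.
#'
#' @param weekly a data frame from [weekly_moving_median()].
#' @param by `"overall"` or `"per_year"`.
#' @return data frame with columns `probe_id` (and `year` if per-year),
#'   `MWavgT`, `date_MWavgT`, `MWmaxT`, `date_MWmaxT`.
#' @export
season_maxima <- function(weekly, by = c("overall", "per_year")) {
  by <- match.arg(by)
  if (nrow(weekly) == 0) stop("empty weekly table", call. = FALSE)
  key <- if (by == "per_year") {
    interaction(weekly$probe_id, format(weekly$date, "%Y"), drop = TRUE)
  } else {
    factor(weekly$probe_id)
  }
  res <- lapply(split(weekly, key), function(w) {
    ia <- which.max(w$WavgT)
    im <- which.max(w$WmaxT)
    out <- data.frame(probe_id = w$probe_id[1],
                      MWavgT = w$WavgT[ia], date_MWavgT = w$date[ia],
                      MWmaxT = w$WmaxT[im], date_MWmaxT = w$date[im])
    if (by == "per_year") out$year <- as.integer(format(w$date[1], "%Y"))
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  cols <- c("probe_id", if (by == "per_year") "year",
            "MWavgT", "date_MWavgT", "MWmaxT", "date_MWmaxT")
  out[, cols]
}

#' Per-group summary of the weekly metrics
#'
#' Unweighted mean and standard deviation of each weekly metric over all
#' probe-days in each group.
#'
#' @param weekly a data frame from [weekly_moving_median()].
#' @param groups named character vector mapping `probe_id` to a group label.
#' @return data frame with one row per group and metric: `group`, `metric`,
#'   `mean`, `sd`, `n`.
#' @export
site_summary <- function(weekly, groups) {
  g <- groups[weekly$probe_id]
  if (anyNA(g)) {
    stop("every probe_id needs a group label", call. = FALSE)
  }
  res <- lapply(split(weekly, g), function(w) {
    data.frame(metric = c("WminT", "WavgT", "WmaxT"),
               mean = c(mean(w$WminT), mean(w$WavgT), mean(w$WmaxT)),
               sd = c(sd(w$WminT), sd(w$WavgT), sd(w$WmaxT)),
               n = nrow(w))
  })
  out <- do.call(rbind, Map(function(d, nm) {d$group <- nm; d},
                            res, names(res)))
  rownames(out) <- NULL
  out[, c("group", "metric", "mean", "sd", "n")]
}

#' Metric tables for a whole study
#'
#' Convenience wrapper running [daily_summaries()], [weekly_moving_median()]
#' and [season_maxima()] over every probe of a (QC'd) study.
#'
#' @param study a `therm_study`.
#' @param completeness_frac,window_days,min_days,align,by passed through.
#' @return list with data frames `daily`, `weekly`, `season`.
#' @export
study_metrics <- function(study, completeness_frac = 0.75, window_days = 7,
                          min_days = 4, align = "center", by = "overall") {
  interval <- study$params$sampling_interval %||% NULL
  daily <- do.call(rbind, lapply(study$series, daily_summaries,
                                 completeness_frac = completeness_frac,
                                 sampling_interval = interval))
  rownames(daily) <- NULL
  weekly <- weekly_moving_median(daily, window_days, min_days, align)
  season <- season_maxima(weekly, by)
  list(daily = daily, weekly = weekly, season = season)
}
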