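# Shared fixtures and independent oracles for the test suite.

# A small single-reach layout for fast simulations.
small_layout <- function(n = 6L, meadow = "Mulkey", treatment = "grazed",
                         length_m = 500, gradient = 0) {
  data.frame(meadow = meadow, reach = paste0(meadow, "_", treatment),
             treatment = treatment, n_probes = as.integer(n),
             length_m = length_m, start_m = 0, gradient_per_100m = gradient)
}

# Deterministic parameters: no noise, flat season, unit slope -- every
# record is the exact closed-form mean + diel curve.
det_params <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, seasonal_amplitude = 0, max_vs_avg_slope = 1),
    list(...))
  do.call(sim_params, args)
}

# Naive rolling-median oracle: per probe, sort-and-pick medians over the
# centred window of calendar days, fully independent of the implementation.
naive_weekly <- function(daily, window_days = 7, min_days = 4) {
  daily <- daily[daily$complete, , drop = FALSE]
  out <- list()
  for (pid in unique(daily$probe_id)) {
    d <- daily[daily$probe_id == pid, ]
    d <- d[order(d$date), ]
    for (i in seq_len(nrow(d))) {
      sel <- abs(as.numeric(d$date - d$date[i])) <= (window_days - 1) / 2
      if (sum(sel) < min_days) next
      pick <- function(v) {
        v <- sort(v[sel])
        k <- length(v)
        if (k %% 2 == 1) v[(k + 1) / 2] else mean(v[k / 2 + 0:1])
      }
      out[[length(out) + 1]] <- data.frame(
        probe_id = pid, date = d$date[i],
        WminT = pick(d$DminT), WavgT = pick(d$DavgT), WmaxT = pick(d$DmaxT),
        n_days = sum(sel))
    }
  }
  do.call(rbind, out)
}

# Exhaustive season-maxima oracle: scan every value of the weekly table.
naive_season <- function(weekly) {
  out <- list()
  for (pid in unique(weekly$probe_id)) {
    w <- weekly[weekly$probe_id == pid, ]
    out[[pid]] <- data.frame(probe_id = pid,
                             MWavgT = max(w$WavgT), MWmaxT = max(w$WmaxT))
  }
  do.call(rbind, out)
}

# Explicit O(n^2) double-sum oracle for Moran's I.
naive_moran <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Random daily metric table honouring DminT <= DavgT <= DmaxT.
random_daily <- function(n_days = 30, probe_id = "p1", start = as.Date("2011-06-01"),
                         gap_prob = 0.1) {
  keep <- runif(n_days) > gap_prob
  avg <- rnorm(n_days, 12, 3)
  lo <- avg - abs(rnorm(n_days, 2, 1))
  hi <- avg + abs(rnorm(n_days, 3, 1))
  data.frame(probe_id = probe_id, date = start + (0:(n_days - 1)),
             DminT = lo, DavgT = avg, DmaxT = hi,
             n_records = 48L, complete = TRUE)[keep, ]
}

quietly_ <- function(expr) suppressWarnings(suppressMessages(expr))

# Calendar day of a timestamp vector (local clock).
day_of <- function(tt) as.Date(strftime(tt, "%Y-%m-%d"))
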