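# Synthetic logger-network generator.
#
# Generative model per probe and day d:
#   m_d  = meadow mean + centred along-stream offset + summer half-sine
#   M_d  = m_d + alpha_d                (spatially correlated AR(1) anomaly)
#   W_d  = centred 7-day running median of M_d
#   A_d  = max(min_amplitude,
#              A_base + (slope - 1) * (W_d - t_ref) - (M_d - W_d))
#   T(t) = M_d + A_d * cos(2*pi*(hour - 16)/24) + eps(t)
# so that, away from the amplitude floor, the day's peak is
#   M_d + A_d = A_base + slope * W_d - (slope - 1) * t_ref:
# the daily maximum tracks the weekly average with slope `max_vs_avg_slope`
# for every source of variation (seasonal, anomaly, along-stream offset),
# while the daily mean is untouched. The deficit (M_d - W_d) acts like
# thermal inertia: days warmer than their surrounding week swing a little
# less about their mean.
# The anomaly field is a space-time process on a fixed 25 m grid per meadow
# (AR(1) across days, exponential correlation along the stream), seeded
# independently of the probe set so adding a probe never perturbs others.

FIELD_GRID_M <- 25

# Dates of a year whose week-of-year falls in `weeks` (ISO convention).
week_dates <- function(year, weeks, convention = "iso") {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  days[week_of_year(days, convention) %in% weeks]
}

seasonal_term <- function(doy, params) {
  mid <- params$seasonal_peak_week * 7 - 3.5
  half <- 42 # days; the summer hump spans peak +/- 6 weeks
  xx <- pmin(pmax((doy - (mid - half)) / (2 * half), 0), 1)
  # centre over the default summer window (weeks 24-31) so meadow_means are
  # approximately the expected window means of the daily average temperature
  x0 <- pmin(pmax((161:217 - (mid - half)) / (2 * half), 0), 1)
  params$seasonal_amplitude * (sin(pi * xx) - mean(sin(pi * x0)))
}

centred_running_median <- function(x, k = 7) {
  n <- length(x)
  h <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

.field_cache <- new.env(parent = emptyenv())

# Daily anomaly field for one meadow and year: matrix n_days x n_grid with
# stationary sd = noise_sd, day-to-day AR(1) phi, and exponential spatial
# correlation exp(-dist/spatial_range) along the grid. The field is a pure
# function of its arguments (seeded by meadow and year, not by the probe
# set), so results are memoised within a session.
meadow_field <- function(params, meadow, year, n_days, grid) {
  key <- paste(params$seed, meadow, year, n_days, length(grid),
               params$noise_sd, params$ar1_phi, params$spatial_range,
               sep = "|")
  hit <- .field_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- meadow_field_raw(params, meadow, year, n_days, grid)
  if (length(ls(.field_cache)) > 64) {
    rm(list = ls(.field_cache), envir = .field_cache)
  }
  .field_cache[[key]] <- out
  out
}

meadow_field_raw <- function(params, meadow, year, n_days, grid) {
  ng <- length(grid)
  if (params$noise_sd == 0 || n_days == 0) {
    return(matrix(0, n_days, ng))
  }
  r <- if (params$spatial_range > 0) exp(-FIELD_GRID_M / params$spatial_range) else 0
  phi <- params$ar1_phi
  with_seed(hash_seed(params$seed, "field", meadow, year), {
    z <- matrix(rnorm(n_days * ng), n_days, ng)
    # spatial AR(1) along the grid (exponential correlation is Markov in 1-D)
    if (ng > 1 && r > 0) {
      for (k in 2:ng) z[, k] <- r * z[, k - 1] + sqrt(1 - r^2) * z[, k]
    }
    # temporal AR(1) across days
    if (n_days > 1 && phi > 0) {
      for (d in 2:n_days) z[d, ] <- phi * z[d - 1, ] + sqrt(1 - phi^2) * z[d, ]
    }
    params$noise_sd * z
  })
}

meadow_slope <- function(params, meadow) {
  s <- params$max_vs_avg_slope
  if (length(s) == 1 && is.null(names(s))) return(as.numeric(s))
  out <- s[[as.character(meadow)]]
  if (is.null(out)) stop(sprintf("no max_vs_avg_slope for meadow '%s'", meadow),
                         call. = FALSE)
  as.numeric(out)
}

resolve_gradient <- function(meta, params) {
  g <- meta$gradient_per_100m
  if (!is.null(g) && length(g) == 1 && is.finite(g)) return(as.numeric(g))
  tr <- as.character(meta$treatment)
  if (tr %in% names(params$gradient_per_100m)) {
    as.numeric(params$gradient_per_100m[[tr]])
  } else 0
}

#' Simulate the temperature series of one probe
#'
#' Evaluates the generative model for a single probe over the requested
#' weeks and years. Deterministic given `params$seed`; the spatially
#' correlated anomaly field is derived from the meadow (not the probe set),
#' and record-level noise from the probe id.
#'
#' @param meta one-row data frame (or list) of probe metadata; fields used:
#'   `probe_id`, `meadow`, `treatment`, `distance_m`, `solar_pct`, and
#'   optionally `reach_start_m`, `reach_length_m`, `gradient_per_100m`.
#' @param params a [sim_params()] object.
#' @param weeks integer vector of weeks of year, within 1..53.
#' @param years integer vector of calendar years.
#' @return a [temp_series()] with `weeks x 7 x (1440 / sampling_interval)`
#'   records per year.
#' @export
simulate_series <- function(meta, params, weeks = 24:31, years = 2010) {
  meta <- as.list(meta)
  if (length(weeks) == 0) stop("empty week range", call. = FALSE)
  if (any(weeks < 1 | weeks > 53)) stop("weeks must lie in 1..53", call. = FALSE)
  base <- deterministic_daily_mean(meta, params)
  s <- meadow_slope(params, meta$meadow)
  sunny <- meta$solar_pct >= 98
  a_base <- if (sunny) params$diel_amplitude_sunny else params$diel_amplitude_shaded
  interval <- params$sampling_interval
  hours <- seq(0, 24 - interval / 60, by = interval / 60)
  diel <- cos(2 * pi * (hours - 16) / 24)
  grid <- field_grid(meta)
  out_time <- vector("list", length(years))
  out_temp <- vector("list", length(years))
  for (yi in seq_along(years)) {
    year <- years[yi]
    dates <- week_dates(year, weeks)
    nd <- length(dates)
    m_d <- base$level + seasonal_term(as.POSIXlt(dates)$yday + 1, params)
    fld <- meadow_field(params, meta$meadow, year, nd, grid)
    gi <- which.min(abs(grid - base$pos_abs))
    M_d <- m_d + fld[, gi]
    W_d <- centred_running_median(M_d, 7)
    A_d <- pmax(params$min_amplitude,
                a_base + (s - 1) * (W_d - params$t_ref) - (M_d - W_d))
    temp <- rep(M_d, each = length(hours)) +
      rep(A_d, each = length(hours)) * rep(diel, nd)
    if (params$sample_noise_sd > 0) {
      # record-level micro-fluctuation: AR(1) at the sample scale with a
      # 3 h correlation time (water temperature is smooth at 20-30 min)
      phi_s <- exp(-interval / 180)
      eps <- with_seed(hash_seed(params$seed, "probe", meta$probe_id, year), {
        e <- stats::filter(rnorm(length(temp), 0, sqrt(1 - phi_s^2)),
                           phi_s, "recursive", init = rnorm(1))
        params$sample_noise_sd * as.numeric(e)
      })
      temp <- temp + eps
    }
    t0 <- as.POSIXct(paste(rep(dates, each = length(hours))),
                     tz = "UTC") + rep(hours, nd) * 3600
    out_time[[yi]] <- t0
    out_temp[[yi]] <- temp
  }
  temp_series(as.character(meta$probe_id),
              do.call(c, out_time), unlist(out_temp))
}

# Deterministic daily-mean level of a probe (no seasonal term): meadow
# baseline + centred gradient offset + optional shading mean effect.
deterministic_daily_mean <- function(meta, params) {
  meadow <- as.character(meta$meadow)
  mu <- params$meadow_means[[meadow]] %||% stop(
    sprintf("meadow '%s' has no entry in params$meadow_means", meadow),
    call. = FALSE)
  g <- resolve_gradient(meta, params)
  s <- meadow_slope(params, meadow)
  L <- meta$reach_length_m %||% 0
  if (is.na(L)) L <- 0
  offset <- (g / s) * (meta$distance_m - L / 2) / 100
  shade_shift <- if (meta$solar_pct < 98) params$shading_mean_effect else 0
  start <- meta$reach_start_m %||% 0
  if (is.na(start)) start <- 0
  list(level = mu + offset + shade_shift,
       pos_abs = start + meta$distance_m)
}

field_grid <- function(meta) {
  start <- meta$reach_start_m %||% 0
  if (is.na(start)) start <- 0
  L <- meta$reach_length_m %||% 0
  if (is.na(L)) L <- 0
  total <- max(start + L, start + meta$distance_m, FIELD_GRID_M)
  seq(0, ceiling(total / FIELD_GRID_M) * FIELD_GRID_M, by = FIELD_GRID_M)
}

#' Default layout of the synthetic probe network
#'
#' Three meadows: one partially grazed (a grazed reach upstream of a fenced
#' ungrazed exclosure reach) and two rested meadows, with 30/30/21 probes.
#' Reach-level downstream gradients of the daily maximum are +0.41 degC per
#' 100 m in the grazed reach, -0.25 in the exclosure, and 0 in the rested
#' meadows.
#'
#' @return data frame with one row per reach: `meadow`, `reach`, `treatment`,
#'   `n_probes`, `length_m`, `start_m`, `gradient_per_100m`.
#' @export
default_layout <- function() {
  data.frame(
    meadow = c("Mulkey", "Mulkey", "Ramshaw", "BigWhitney"),
    reach = c("Mulkey_grazed", "Mulkey_ungrazed", "Ramshaw", "BigWhitney"),
    treatment = c("grazed", "ungrazed", "ungrazed", "ungrazed"),
    n_probes = c(17L, 13L, 30L, 21L),
    length_m = c(900, 1200, 1500, 1200),
    start_m = c(0, 900, 0, 0),
    gradient_per_100m = c(0.41, -0.25, 0, 0)
  )
}

meadow_origin <- function(meadow) {
  origins <- list(Mulkey = c(36.4053, -118.1950),
                  Ramshaw = c(36.3481, -118.2480),
                  BigWhitney = c(36.4397, -118.2699))
  origins[[meadow]] %||% c(36.40, -118.20)
}

# Probe metadata for one reach. Positions span [0, length] with hashed
# jitter on interior probes; covariates are drawn from treatment-dependent
# distributions (more willow and shade where cattle are excluded).
reach_metadata <- function(reach, params, id_prefix, n_existing) {
  n <- reach$n_probes
  seed <- hash_seed(params$seed, "meta", reach$reach)
  with_seed(seed, {
    pos <- seq(0, reach$length_m, length.out = n)
    if (n > 2) {
      step <- reach$length_m / (n - 1)
      pos[2:(n - 1)] <- pos[2:(n - 1)] + runif(n - 2, -0.3, 0.3) * step
      pos <- sort(pos)
    }
    grazed <- reach$treatment == "grazed"
    p_sunny <- if (grazed) 0.954 else 0.841
    sunny <- runif(n) < p_sunny
    solar <- ifelse(sunny, runif(n, 98, 100), runif(n, 60, 97.9))
    veg_levels <- c("willow", "sedge", "grass", "none")
    veg_prob <- if (grazed) c(0.12, 0.50, 0.26, 0.12) else c(0.50, 0.28, 0.15, 0.07)
    vegetation <- sample(veg_levels, n, replace = TRUE, prob = veg_prob)
    habitat <- sample(c("pool", "riffle", "underbank"), n, replace = TRUE,
                      prob = c(0.45, 0.45, 0.10))
    depth_cm <- pmax(5, rnorm(n, 35, 12))
    velocity_ms <- pmax(0.01, rnorm(n, 0.2, 0.1))
    origin <- meadow_origin(reach$meadow)
    abs_pos <- reach$start_m + pos
    lat <- origin[1] - abs_pos / 111320
    lon <- origin[2] + 3e-4 * sin(abs_pos / 150) +
      (if (reach$meadow == "Ramshaw") abs_pos / 150000 else -abs_pos / 250000)
    data.frame(
      probe_id = sprintf("%s%02d", id_prefix, n_existing + seq_len(n)),
      meadow = reach$meadow, reach = reach$reach, treatment = reach$treatment,
      lat = lat, lon = lon, distance_m = pos,
      reach_start_m = reach$start_m, reach_length_m = reach$length_m,
      gradient_per_100m = reach$gradient_per_100m,
      depth_cm = depth_cm, velocity_ms = velocity_ms,
      vegetation = vegetation, habitat = habitat,
      solar_pct = solar
    )
  })
}

#' Build a full synthetic study
#'
#' Generates probe metadata and one temperature series per probe for every
#' reach in `layout`. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param layout reach table as returned by [default_layout()]; per-reach
#'   `gradient_per_100m` may be `NA` to fall back on the treatment-level
#'   value in `params`.
#' @param weeks,years study window (weeks of year; calendar years).
#' @return an object of class `therm_study`: list with `probes` (metadata
#'   data frame), `series` (named list of [temp_series()]), `window`, `years`.
#' @examples
#' study <- build_study(sim_params(noise_sd = 0), years = 2010)
#' nrow(study$probes)
#' @export
build_study <- function(params = sim_params(), layout = default_layout(),
                        weeks = 24:31, years = 2010:2012) {
  if (length(weeks) == 0) stop("empty week range", call. = FALSE)
  if (any(layout$n_probes < 2)) {
    stop("each reach needs at least 2 probes", call. = FALSE)
  }
  if (any(layout$length_m <= 0)) {
    stop("reach lengths must be positive", call. = FALSE)
  }
  if (anyDuplicated(layout$reach)) {
    stop("duplicate reach labels in layout", call. = FALSE)
  }
  prefixes <- make.unique(substr(layout$reach, 1, 2), sep = "_")
  metas <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    if (is.na(row$gradient_per_100m)) {
      row$gradient_per_100m <-
        params$gradient_per_100m[[row$treatment]] %||% 0
    }
    metas[[i]] <- reach_metadata(row, params, prefixes[i], 0L)
  }
  probes <- do.call(rbind, metas)
  rownames(probes) <- NULL
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe ids in layout", call. = FALSE)
  }
  series <- lapply(seq_len(nrow(probes)), function(i) {
    simulate_series(probes[i, ], params, weeks, years)
  })
  names(series) <- probes$probe_id
  structure(list(probes = probes, series = series,
                 window = range(weeks), years = years,
                 params = params),
            class = "therm_study")
}

#' @export
print.therm_study <- function(x, ...) {
  cat(sprintf("<therm_study> %d probes in %d reaches; weeks %d-%d, years %s\n",
              nrow(x$probes), length(unique(x$probes$reach)),
              x$window[1], x$window[2],
              paste(x$years, collapse = ",")))
  nrec <- sum(vapply(x$series, length, numeric(1)))
  cat(sprintf("  %d temperature records\n", nrec))
  invisible(x)
}

#' Simulate a bank willow survey
#'
#' Draws willow positions along the bank of each treatment reach and
#' truncated-normal heights. Defaults emulate a strong exclosure effect:
#' dense tall willows inside the fence, sparse short willows outside.
#'
#' @param reach_length_m named numeric, bank length (m) per treatment.
#' @param density willows per metre, named as `reach_length_m`.
#' @param height_mean_cm,height_sd_cm truncated-normal height parameters (cm).
#' @param seed integer seed.
#' @param exact_counts if `TRUE`, use `round(density * length)` willows per
#'   reach instead of a Poisson draw.
#' @param clustered if `TRUE`, positions are drawn around Poisson cluster
#'   centres instead of uniformly.
#' @param min_height_cm truncation floor for heights.
#' @return data frame of class `willow_survey` with columns `reach`,
#'   `treatment`, `position_m`, `height_cm`.
#' @export
simulate_willows <- function(reach_length_m = c(ungrazed = 1200, grazed = 900),
                             density = c(ungrazed = 980 / 1200, grazed = 75 / 900),
                             height_mean_cm = c(ungrazed = 92, grazed = 43),
                             height_sd_cm = c(ungrazed = 56, grazed = 29),
                             seed = 1L, exact_counts = FALSE,
                             clustered = FALSE, min_height_cm = 1) {
  if (any(reach_length_m < 0)) stop("reach lengths must be >= 0", call. = FALSE)
  if (any(density <= 0)) stop("densities must be positive", call. = FALSE)
  treatments <- names(reach_length_m)
  out <- lapply(treatments, function(tr) {
    L <- reach_length_m[[tr]]
    lambda <- density[[tr]] * L
    with_seed(hash_seed(seed, "willow", tr), {
      n <- if (exact_counts) round(lambda) else rpois(1, lambda)
      if (n == 0) {
        return(data.frame(reach = character(), treatment = character(),
                          position_m = numeric(), height_cm = numeric()))
      }
      if (clustered) {
        k <- max(1, rpois(1, n / 8))
        centres <- runif(k, 0, L)
        pos <- pmin(pmax(centres[sample.int(k, n, replace = TRUE)] +
                           rnorm(n, 0, L / 100), 0), L)
      } else {
        pos <- runif(n, 0, L)
      }
      mu <- height_mean_cm[[tr]]
      sdv <- height_sd_cm[[tr]]
      if (sdv == 0) {
        h <- rep(mu, n)
      } else {
        lo <- pnorm((min_height_cm - mu) / sdv)
        h <- mu + sdv * qnorm(runif(n, lo, 1))
      }
      data.frame(reach = tr, treatment = tr,
                 position_m = sort(pos), height_cm = h)
    })
  })
  survey <- do.call(rbind, out)
  rownames(survey) <- NULL
  attr(survey, "reach_length_m") <- reach_length_m
  class(survey) <- c("willow_survey", "data.frame")
  survey
}

#' Inject out-of-water artifacts into a series
#'
#' Replaces the records of the listed days with air-like readings: the same
#' daily mean but a diel swing rescaled to 2.2 times the largest clean daily
#' range, plus noise. The days are flagged `out_of_water` so the QC stage
#' can remove them.
#'
#' @param series a [temp_series()].
#' @param days `Date` vector of days to corrupt (must be present in the
#'   series); empty vector returns the series unchanged.
#' @param seed integer seed for the added noise.
#' @return the corrupted [temp_series()] with updated flags.
#' @export
inject_out_of_water <- function(series, days, seed = 1L) {
  days <- as.Date(days)
  if (length(days) == 0) return(series)
  dates <- clock_date(series$time)
  if (!all(days %in% dates)) {
    stop("all injected days must be present in the series", call. = FALSE)
  }
  clean <- !(dates %in% days)
  rng <- tapply(series$temp_c[clean], dates[clean],
                function(v) diff(range(v)))
  r_clean <- if (length(rng)) max(rng) else 0
  target <- if (r_clean > 0) 2.2 * r_clean else 16
  temp <- series$temp_c
  hours <- as.numeric(difftime(series$time, as.POSIXct(paste(dates), tz = "UTC"),
                               units = "hours"))
  for (d in as.list(days)) {
    idx <- which(dates == d)
    mu <- mean(temp[idx])
    v <- mu + (target / 2) * cos(2 * pi * (hours[idx] - 15) / 24) +
      with_seed(hash_seed(seed, "oow", series$probe_id, format(d)),
                rnorm(length(idx), 0, target / 10))
    span <- diff(range(v))
    temp[idx] <- mu + (v - mean(v)) * (target / span)
  }
  flags <- rbind(series$flags,
                 data.frame(date = days, flag = "out_of_water"))
  flags <- flags[!duplicated(flags), , drop = FALSE]
  temp_series(series$probe_id, series$time, temp, flags)
}
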