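# Climate-scenario projection of maximum water temperatures.
#
# The response model regresses the observed daily maximum (DmaxT) on the
# weekly average (WavgT) with a calendar-date random intercept; warming
# scenarios shift the baseline WavgT by a water-temperature delta and the
# prediction bands (50/95/99%) are read as recurrence intervals (2, 20 and
# 100 years).

Z_BANDS <- c(`50` = qnorm(0.75), `95` = qnorm(0.975), `99` = qnorm(0.995))

#' Join daily maxima with weekly averages per probe-day
#'
#' @param daily,weekly metric tables from [daily_summaries()] and
#'   [weekly_moving_median()].
#' @param probes probe metadata with `probe_id` and `meadow`.
#' @return data frame with `probe_id`, `date`, `meadow`, `DmaxT`, `WavgT`.
#' @export
max_avg_table <- function(daily, weekly, probes) {
  d <- merge(daily[daily$complete %||% rep(TRUE, nrow(daily)), , drop = FALSE]
             [, c("probe_id", "date", "DmaxT")],
             weekly[, c("probe_id", "date", "WavgT")],
             by = c("probe_id", "date"))
  d <- merge(d, probes[, c("probe_id", "meadow")], by = "probe_id")
  d[order(d$probe_id, d$date), ]
}

#' Fit the maximum-versus-average temperature response
#'
#' Fits, per meadow, the linear mixed model `DmaxT ~ WavgT + (1 | date)`
#' (calendar date shared across probes as the repeated-measures random
#' effect), and additionally the all-meadow interaction model
#' `DmaxT ~ WavgT * meadow + (1 | date)` whose interaction terms are the
#' slope differences against the reference meadow. When a meadow's mixed
#' fit is degenerate (zero residual variance) an ordinary regression is
#' used and flagged.
#'
#' @param data a table from [max_avg_table()].
#' @param reference meadow used as the interaction reference (default: the
#'   meadow with the steepest single-meadow slope).
#' @param sd_mode `"total"`: scenario band sd is
#'   `sqrt(residual^2 + date-intercept^2)` (across-day, across-site
#'   extremes); `"residual"`: residual sd only.
#' @param min_probe_days minimum probe-days per meadow.
#' @return object of class `projection_model`; see [projection_model()].
#' @export
fit_max_vs_avg <- function(data, reference = NULL,
                           sd_mode = c("total", "residual"),
                           min_probe_days = 30) {
  sd_mode <- match.arg(sd_mode)
  data$meadow <- as.character(data$meadow)
  counts <- table(data$meadow)
  if (any(counts < min_probe_days)) {
    stop(sprintf("meadow(s) with fewer than %d probe-days: %s",
                 min_probe_days,
                 paste(names(counts)[counts < min_probe_days], collapse = ", ")),
         call. = FALSE)
  }
  meadows <- names(counts)
  per <- lapply(meadows, function(m) {
    d <- data[data$meadow == m, ]
    fit <- tryCatch(
      suppressWarnings(
        lmerTest::lmer(DmaxT ~ WavgT + (1 | date), data = d,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))),
      error = function(e) NULL)
    degenerate <- is.null(fit) || sigma(fit) < 1e-6 * max(1, sd(d$DmaxT))
    if (degenerate) {
      lf <- lm(DmaxT ~ WavgT, data = d)
      sm <- summary(lf)$coefficients
      data.frame(meadow = m, intercept = sm[1, 1], slope = sm[2, 1],
                 slope_se = sm[2, 2], sd_date = 0,
                 sd_resid = summary(lf)$sigma, n = nrow(d),
                 baseline_WavgT = mean(d$WavgT), singular = TRUE)
    } else {
      sm <- summary(fit)$coefficients
      vc <- as.data.frame(lme4::VarCorr(fit))
      sd_date <- vc$sdcor[vc$grp == "date"]
      sd_resid <- vc$sdcor[vc$grp == "Residual"]
      data.frame(meadow = m, intercept = sm[1, 1], slope = sm[2, 1],
                 slope_se = sm[2, 2], sd_date = sd_date, sd_resid = sd_resid,
                 n = nrow(d), baseline_WavgT = mean(d$WavgT),
                 singular = lme4::isSingular(fit))
    }
  })
  per <- do.call(rbind, per)
  if (is.null(reference)) reference <- per$meadow[which.max(per$slope)]
  contrasts <- NULL
  if (length(meadows) >= 2) {
    data$meadow_f <- stats::relevel(factor(data$meadow), ref = reference)
    ifit <- tryCatch(
      suppressWarnings(
        lmerTest::lmer(DmaxT ~ WavgT * meadow_f + (1 | date), data = data,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))),
      error = function(e) NULL)
    degenerate_i <- is.null(ifit) ||
      sigma(ifit) < 1e-6 * max(1, sd(data$DmaxT))
    if (degenerate_i) {
      # deterministic relation: plain OLS recovers the exact slope contrasts
      lfit <- lm(DmaxT ~ WavgT * meadow_f, data = data)
      sm <- summary(lfit)$coefficients
      rows <- grep("^WavgT:meadow_f", rownames(sm))
      contrasts <- data.frame(
        meadow = sub("^WavgT:meadow_f", "", rownames(sm)[rows]),
        slope_diff = -sm[rows, "Estimate"],
        se = sm[rows, "Std. Error"], t = -sm[rows, "t value"],
        df = rep(stats::df.residual(lfit), length(rows)),
        p_value = sm[rows, 4])
    } else {
      sm <- summary(ifit)$coefficients
      rows <- grep("^WavgT:meadow_f", rownames(sm))
      contrasts <- data.frame(
        meadow = sub("^WavgT:meadow_f", "", rownames(sm)[rows]),
        slope_diff = -sm[rows, "Estimate"],
        se = sm[rows, "Std. Error"], t = -sm[rows, "t value"],
        df = sm[rows, "df"], p_value = sm[rows, "Pr(>|t|)"])
    }
    rownames(contrasts) <- NULL
  }
  projection_model(per, contrasts = contrasts, reference = reference,
                   sd_mode = sd_mode)
}

#' Projection model object
#'
#' Container for the per-meadow maximum-versus-average response used by
#' [project_scenario()]. Usually produced by [fit_max_vs_avg()], but can be
#' constructed directly from published coefficients.
#'
#' @param meadows data frame with columns `meadow`, `intercept`, `slope`,
#'   and either `sd_total` or both `sd_date` and `sd_resid`; optional
#'   `slope_se`, `baseline_WavgT`, `n`, `singular`.
#' @param contrasts optional data frame of slope differences versus the
#'   reference meadow.
#' @param reference reference meadow label.
#' @param sd_mode `"total"` or `"residual"`, see [fit_max_vs_avg()].
#' @return object of class `projection_model`.
#' @export
projection_model <- function(meadows, contrasts = NULL, reference = NULL,
                             sd_mode = "total") {
  meadows <- as.data.frame(meadows)
  if (!all(c("meadow", "intercept", "slope") %in% names(meadows))) {
    stop("'meadows' needs columns meadow, intercept, slope", call. = FALSE)
  }
  if (!"sd_total" %in% names(meadows)) {
    if (!all(c("sd_date", "sd_resid") %in% names(meadows))) {
      stop("'meadows' needs sd_total, or sd_date and sd_resid", call. = FALSE)
    }
    meadows$sd_total <- if (sd_mode == "total") {
      sqrt(meadows$sd_date^2 + meadows$sd_resid^2)
    } else {
      meadows$sd_resid
    }
  }
  structure(list(meadows = meadows, contrasts = contrasts,
                 reference = reference, sd_mode = sd_mode),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat("Maximum-vs-average temperature response (DmaxT ~ WavgT + (1|date))\n")
  m <- x$meadows
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s slope %.3f%s, intercept %.2f, band sd %.2f degC%s\n",
                m$meadow[i], m$slope[i],
                if (!is.null(m$slope_se)) sprintf(" +/- %.3f", m$slope_se[i]) else "",
                m$intercept[i], m$sd_total[i],
                if (isTRUE(m$singular[i])) " [singular]" else ""))
  }
  if (!is.null(x$contrasts)) {
    cat(sprintf("  slope differences vs %s:\n", x$reference))
    cc <- x$contrasts
    for (i in seq_len(nrow(cc))) {
      cat(sprintf("    -%.3f +/- %.3f for %s (t_%.0f = %.2f, p = %.3g)\n",
                  cc$slope_diff[i], cc$se[i], cc$meadow[i], cc$df[i],
                  cc$t[i], cc$p_value[i]))
    }
  }
  invisible(x)
}

#' @export
coef.projection_model <- function(object, ...) {
  m <- object$meadows
  stats::setNames(m$slope, m$meadow)
}

#' @export
summary.projection_model <- function(object, ...) {
  object$meadows
}

#' @export
predict.projection_model <- function(object, newdata, ...) {
  m <- object$meadows
  idx <- match(newdata$meadow, m$meadow)
  if (anyNA(idx)) stop("unknown meadow in newdata", call. = FALSE)
  mu <- m$intercept[idx] + m$slope[idx] * newdata$WavgT
  out <- data.frame(meadow = newdata$meadow, WavgT = newdata$WavgT,
                    expected_DmaxT = mu)
  for (lv in names(Z_BANDS)) {
    out[[paste0("lo", lv)]] <- mu - Z_BANDS[[lv]] * m$sd_total[idx]
    out[[paste0("hi", lv)]] <- mu + Z_BANDS[[lv]] * m$sd_total[idx]
  }
  out
}

#' Convert an air-temperature increase to a water-temperature increase
#'
#' Fixed linear scaling of water warming per degree of air warming; the
#' default ratio 0.5 is a conservative value below published air-to-water
#' transfer estimates.
#'
#' @param delta_air degC increase in air temperature.
#' @param ratio water-per-air warming ratio, positive.
#' @return degC increase in water temperature.
#' @export
air_to_water <- function(delta_air, ratio = 0.5) {
  if (!is.numeric(ratio) || any(ratio <= 0)) {
    stop("'ratio' must be positive", call. = FALSE)
  }
  delta_air * ratio
}

#' Warming scenario specification
#'
#' @param label scenario name.
#' @param delta_air degC air-temperature increase.
#' @param ratio water-per-air ratio.
#' @param delta_water degC water-temperature increase; defaults to
#'   `delta_air * ratio`.
#' @return one-row data frame with `label`, `delta_air`, `delta_water`.
#' @export
scenario_spec <- function(label, delta_air, ratio = 0.5, delta_water = NULL) {
  if (is.null(delta_water)) delta_water <- air_to_water(delta_air, ratio)
  if (abs(delta_water - delta_air * ratio) > 0.05 + 1e-9) {
    stop("'delta_water' inconsistent with delta_air * ratio", call. = FALSE)
  }
  data.frame(label = label, delta_air = delta_air, delta_water = delta_water)
}

#' The four standard warming scenarios
#'
#' No change, an optimistic +1 degC air scenario, a pessimistic +3.7 degC
#' scenario, and a cataclysmic +5.6 degC scenario, with water deltas at the
#' conventionally reported 1-decimal values (0, 0.5, 1.8, 2.8 degC).
#'
#' @param exact_products if `TRUE`, recompute water deltas as
#'   `delta_air * 0.5` at full precision (1.85 instead of 1.8).
#' @return data frame of scenarios.
#' @export
default_scenarios <- function(exact_products = FALSE) {
  s <- data.frame(label = c("current", "optimistic", "pessimistic", "cataclysmic"),
                  delta_air = c(0, 1, 3.7, 5.6),
                  delta_water = c(0, 0.5, 1.8, 2.8))
  if (exact_products) s$delta_water <- s$delta_air * 0.5
  s
}

#' Project a warming scenario
#'
#' Shifts each meadow's baseline weekly average temperature by the
#' scenario's water delta and returns the expected daily maximum with
#' 50/95/99% normal prediction bands, whose upper limits are read as the
#' 2-, 20- and 100-year recurrence temperatures.
#'
#' @param model a [projection_model()].
#' @param scenario one-row data frame from [scenario_spec()] (or one row of
#'   [default_scenarios()]).
#' @param baseline named numeric of baseline mean WavgT per meadow; default
#'   is the model's stored baseline (mean WavgT over all probe-days).
#' @param allow_cooling permit negative water deltas.
#' @return data frame with one row per meadow: scenario label, baseline and
#'   shifted WavgT, `expected_DmaxT`, and band columns `lo50`..`hi99`.
#' @export
project_scenario <- function(model, scenario, baseline = NULL,
                             allow_cooling = FALSE) {
  m <- model$meadows
  dw <- scenario$delta_water
  if (dw < 0 && !allow_cooling) {
    stop("negative water delta; set allow_cooling = TRUE to permit",
         call. = FALSE)
  }
  if (is.null(baseline)) {
    if (!"baseline_WavgT" %in% names(m)) {
      stop("no baseline WavgT available; pass 'baseline'", call. = FALSE)
    }
    baseline <- stats::setNames(m$baseline_WavgT, m$meadow)
  }
  w0 <- baseline[m$meadow]
  if (anyNA(w0)) stop("baseline missing for some meadow", call. = FALSE)
  shifted <- w0 + dw
  pred <- predict(model, data.frame(meadow = m$meadow, WavgT = shifted))
  out <- cbind(data.frame(scenario = scenario$label,
                          delta_water = dw,
                          meadow = m$meadow,
                          baseline_WavgT = as.numeric(w0),
                          shifted_WavgT = as.numeric(shifted)),
               pred[, setdiff(names(pred), c("meadow", "WavgT"))])
  rownames(out) <- NULL
  out
}

#' Full scenario-by-meadow recurrence report
#'
#' Runs [project_scenario()] for every scenario and stacks the rows; the
#' print method renders a 1-decimal table with the recurrence labels
#' (2-year, 20-year and 100-year temperatures) on the band upper limits.
#' Full precision is retained in the returned data frame.
#'
#' @param model a [projection_model()].
#' @param scenarios data frame of scenarios, default [default_scenarios()].
#' @param baseline,allow_cooling passed to [project_scenario()].
#' @return object of class `recurrence_table` (a data frame).
#' @export
recurrence_table <- function(model, scenarios = default_scenarios(),
                             baseline = NULL, allow_cooling = FALSE) {
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    project_scenario(model, scenarios[i, ], baseline, allow_cooling)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recurrence_table", "data.frame")
  out
}

#' @export
print.recurrence_table <- function(x, digits = 1, ...) {
  r <- function(v) sprintf(paste0("%.", digits, "f"), round_half_up(v, digits))
  cat("Expected daily maxima with recurrence bands (degC)\n")
  cat(sprintf("  %-12s %-12s %6s %6s %8s %13s %13s %13s\n",
              "scenario", "meadow", "WavgT", "+dW", "DmaxT",
              "2-yr band", "20-yr band", "100-yr band"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %-12s %6s %6s %8s [%s:%s] [%s:%s] [%s:%s]\n",
                x$scenario[i], x$meadow[i], r(x$shifted_WavgT[i]),
                r(x$delta_water[i]), r(x$expected_DmaxT[i]),
                r(x$lo50[i]), r(x$hi50[i]), r(x$lo95[i]), r(x$hi95[i]),
                r(x$lo99[i]), r(x$hi99[i])))
  }
  invisible(x)
}
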