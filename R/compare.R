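# Grazing analyses: vegetation and shading contrasts, downstream warming
# gradients per reach, and multi-scale mixed-model temperature contrasts.

#' Chi-squared test of vegetation class by treatment
#'
#' Pearson chi-squared test (no continuity correction) of a 2 x k
#' treatment-by-vegetation contingency table.
#'
#' @param counts 2 x k matrix of nonnegative integer counts, k >= 2.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
vegetation_type_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2) {
    stop("'counts' must be a 2 x k table with k >= 2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must hold nonnegative integers", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("a cell has expected count 0; merge sparse vegetation classes",
         call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = expected)
}

#' Binarize solar exposure at the near-total threshold
#'
#' @param solar_pct numeric in `[0, 100]`.
#' @return integer vector: 1 when exposure >= 98 (essentially unshaded),
#'   0 otherwise.
#' @export
binarize_solar <- function(solar_pct) {
  if (any(!is.finite(solar_pct)) || any(solar_pct < 0 | solar_pct > 100)) {
    stop("'solar_pct' must lie in [0, 100]", call. = FALSE)
  }
  as.integer(solar_pct >= 98)
}

#' Logistic comparison of sun exposure between treatments
#'
#' Logistic regression of the binary sunny indicator on treatment. Complete
#' separation is detected and reported, with Fisher's exact test as the
#' fallback p-value.
#'
#' @param sunny 0/1 vector (see [binarize_solar()]).
#' @param treatment factor-like with both treatments present.
#' @return list with `z`, `p_value`, `proportions` (per-treatment sunny
#'   fraction), `separation`, `method`.
#' @export
shade_logistic <- function(sunny, treatment) {
  treatment <- factor(treatment)
  if (nlevels(treatment) != 2) {
    stop("'treatment' must have exactly two levels", call. = FALSE)
  }
  props <- tapply(sunny, treatment, mean)
  sep <- any(props %in% c(0, 1))
  if (sep) {
    tab <- table(factor(sunny, levels = 0:1), treatment)
    ft <- fisher.test(tab)
    return(list(z = NA_real_, p_value = ft$p.value, proportions = props,
                separation = TRUE, method = "fisher"))
  }
  fit <- glm(sunny ~ treatment, family = binomial())
  sm <- summary(fit)$coefficients
  list(z = unname(sm[2, 3]), p_value = unname(sm[2, 4]), proportions = props,
       separation = FALSE, method = "logistic")
}

#' Willow spacing by treatment
#'
#' Consecutive spacing of willows along the bank per treatment, with a
#' spatially adjusted comparison of spacings between treatments
#' (see [autoregressive_adjusted_model()]; the coordinate is the midpoint
#' of each gap).
#'
#' @param survey a `willow_survey` data frame (see [simulate_willows()]).
#' @return list with `summary` (per-treatment count, mean spacing, density)
#'   and `comparison` (an `adjusted_fit`, or `NULL` when a treatment has a
#'   single willow).
#' @export
willow_spacing <- function(survey) {
  lens <- attr(survey, "reach_length_m")
  parts <- split(survey, survey$treatment)
  sumr <- do.call(rbind, lapply(names(parts), function(tr) {
    p <- sort(parts[[tr]]$position_m)
    L <- if (!is.null(lens) && tr %in% names(lens)) lens[[tr]] else max(p)
    data.frame(treatment = tr, n = length(p),
               mean_spacing_m = if (length(p) >= 2) mean(diff(p)) else NA_real_,
               density_per_m = length(p) / L)
  }))
  ok <- vapply(parts, nrow, integer(1)) >= 2
  comparison <- NULL
  if (all(ok)) {
    sp <- lapply(parts, function(d) {
      p <- sort(d$position_m)
      data.frame(treatment = d$treatment[1], spacing = diff(p),
                 mid = (p[-1] + p[-length(p)]) / 2)
    })
    sp <- do.call(rbind, sp)
    comparison <- tryCatch(
      suppressWarnings(
        autoregressive_adjusted_model(sp$spacing, sp$treatment, sp$mid)),
      error = function(e) NULL)
  }
  list(summary = sumr, comparison = comparison)
}

#' Willow heights by treatment
#'
#' Descriptive statistics and a spatially adjusted treatment comparison of
#' willow heights.
#'
#' @param survey a `willow_survey` data frame.
#' @return list with `summary` (per-treatment mean and sd, cm) and
#'   `comparison` (an `adjusted_fit`).
#' @export
willow_heights <- function(survey) {
  parts <- split(survey, survey$treatment)
  sumr <- do.call(rbind, lapply(names(parts), function(tr) {
    h <- parts[[tr]]$height_cm
    data.frame(treatment = tr, n = length(h),
               mean_cm = mean(h), sd_cm = sd(h))
  }))
  comparison <- tryCatch(
    suppressWarnings(
      autoregressive_adjusted_model(survey$height_cm, survey$treatment,
                                    survey$position_m)),
    error = function(e) NULL)
  list(summary = sumr, comparison = comparison)
}

#' Downstream gradient of the season maximum temperature
#'
#' Per-reach ordinary least squares of `MWmaxT` on along-stream distance,
#' reported as degC per 100 m. Reaches are fitted separately (no pooled
#' interaction model, since slopes may differ in sign between treatments).
#' Moran's I of the residuals (against probe coordinates when available,
#' otherwise along-stream distance) is attached per reach.
#'
#' @param season a data frame from [season_maxima()].
#' @param probes probe metadata with `probe_id`, `distance_m`, `reach`, and
#'   optionally `lon`/`lat`.
#' @return object of class `gradient_fit`: data frame with one row per
#'   reach (`reach`, `n`, `slope_per_100m`, `se_per_100m`, `t`, `df`,
#'   `p_value`, `moran_i`, `moran_p`).
#' @export
gradient_regression <- function(season, probes) {
  d <- merge(season, probes, by = "probe_id")
  rows <- lapply(split(d, d$reach), function(r) {
    if (nrow(r) < 3) {
      stop(sprintf("reach %s has fewer than 3 probes", r$reach[1]),
           call. = FALSE)
    }
    if (length(unique(r$distance_m)) < 2) {
      stop(sprintf("reach %s: distances are all equal", r$reach[1]),
           call. = FALSE)
    }
    fit <- lm(MWmaxT ~ distance_m, data = r)
    sm <- suppressWarnings(summary(fit))$coefficients
    mor <- tryCatch({
      coords <- if (all(c("lon", "lat") %in% names(r))) {
        r[, c("lon", "lat")]
      } else {
        r$distance_m
      }
      suppressWarnings(morans_i(resid(fit), inverse_distance_weights(coords)))
    }, error = function(e) NULL)
    data.frame(reach = r$reach[1], n = nrow(r),
               slope_per_100m = sm[2, 1] * 100,
               se_per_100m = sm[2, 2] * 100,
               t = sm[2, 3], df = nrow(r) - 2, p_value = sm[2, 4],
               moran_i = if (is.null(mor)) NA_real_ else mor$I,
               moran_p = if (is.null(mor)) NA_real_ else mor$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gradient_fit", "data.frame")
  out
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("Downstream gradients of MWmaxT (degC per 100 m)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s %+0.3f +/- %.3f  t_%d = %.2f, p = %.3g\n",
                x$reach[i], x$slope_per_100m[i], x$se_per_100m[i],
                x$df[i], x$t[i], x$p_value[i]))
  }
  invisible(x)
}

#' @export
coef.gradient_fit <- function(object, ...) {
  setNames(object$slope_per_100m, object$reach)
}

#' Aggregate weekly metrics over time units
#'
#' Means of `WminT`/`WavgT`/`WmaxT` within each probe (or group) by
#' time-unit cell. Aggregating at coarser scales removes temporal
#' autocorrelation at the cost of fewer observations.
#'
#' @param weekly a data frame from [weekly_moving_median()].
#' @param scale `"week"`, `"month"` or `"year"` (calendar units).
#' @param mode `"per_probe"` (keep probes; a probe random intercept is then
#'   used downstream) or `"per_reach"` (average over the probes of a group
#'   first, one value per group and unit).
#' @param groups named character vector mapping `probe_id` to a group.
#' @return data frame with columns `group`, `probe_id` (per_probe mode),
#'   `unit`, `time` (numeric, in units of `scale`), the three metrics, and
#'   `n`; attribute `scale` records the aggregation scale.
#' @export
aggregate_metric <- function(weekly, scale = c("month", "week", "year"),
                             mode = c("per_probe", "per_reach"), groups) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  if (nrow(weekly) == 0) stop("empty weekly table", call. = FALSE)
  g <- groups[weekly$probe_id]
  if (anyNA(g)) stop("every probe_id needs a group label", call. = FALSE)
  unit <- switch(scale,
    year = format(weekly$date, "%Y"),
    month = format(weekly$date, "%Y-%m"),
    week = paste0(strftime(weekly$date, "%G"), "-W", strftime(weekly$date, "%V")))
  div <- switch(scale, year = 365.25, month = 30.4375, week = 7)
  key <- if (mode == "per_probe") {
    paste(g, weekly$probe_id, unit, sep = "\r")
  } else {
    paste(g, unit, sep = "\r")
  }
  agg <- lapply(split(seq_len(nrow(weekly)), key), function(idx) {
    data.frame(group = g[idx[1]],
               probe_id = if (mode == "per_probe") weekly$probe_id[idx[1]] else NA,
               unit = unit[idx[1]],
               time = mean(as.numeric(weekly$date[idx])) / div,
               WminT = mean(weekly$WminT[idx]),
               WavgT = mean(weekly$WavgT[idx]),
               WmaxT = mean(weekly$WmaxT[idx]),
               n = length(idx))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  if (mode == "per_reach") out$probe_id <- NULL
  attr(out, "scale") <- scale
  attr(out, "mode") <- mode
  out
}

# Direct group-mean contrasts used when the mixed model is degenerate
# (residual variance numerically zero, e.g. noise-free simulations).
degenerate_contrasts <- function(agg, metric) {
  mu <- tapply(agg[[metric]], agg$group, mean)
  nm <- names(mu)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(metric = metric, pair = paste(p[1], "-", p[2]),
               difference = unname(mu[p[1]] - mu[p[2]]),
               se = 0, df = NA_real_,
               t = if (mu[p[1]] == mu[p[2]]) 0 else Inf,
               p_value = if (mu[p[1]] == mu[p[2]]) 1 else 0)
  }))
}

#' Mixed-model contrasts of temperature metrics between groups
#'
#' Fits, for each metric, a linear mixed model of the aggregated metric on
#' the group label with a random intercept for the time unit (and for the
#' probe in `per_probe` mode), and returns all pairwise group contrasts
#' with Satterthwaite degrees of freedom. Moran's I of the residuals
#' against temporal distance is attached per metric.
#'
#' @param agg an aggregated table from [aggregate_metric()].
#' @param metrics which metrics to contrast.
#' @return object of class `thermal_contrasts`: data frame with columns
#'   `metric`, `scale`, `pair`, `difference`, `se`, `df`, `t`, `p_value`,
#'   `moran_i`, `moran_p`, `singular`.
#' @export
compare_groups_lmm <- function(agg, metrics = c("WminT", "WavgT", "WmaxT")) {
  if (length(unique(agg$group)) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (length(unique(agg$unit)) < 2) {
    stop("need at least 2 time units", call. = FALSE)
  }
  per_probe <- "probe_id" %in% names(agg)
  scale <- attr(agg, "scale") %||% NA_character_
  res <- lapply(metrics, function(metric) {
    dat <- data.frame(value = agg[[metric]], group = factor(agg$group),
                      unit = factor(agg$unit), time = agg$time)
    if (per_probe) dat$probe_id <- factor(agg$probe_id)
    form <- if (per_probe) {
      value ~ group + (1 | unit) + (1 | probe_id)
    } else {
      value ~ group + (1 | unit)
    }
    fit <- tryCatch(
      suppressWarnings(
        suppressMessages(
          lmerTest::lmer(form, data = dat,
                         control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    degenerate <- is.null(fit) ||
      sigma(fit) < 1e-6 * max(1, sd(dat$value))
    if (degenerate) {
      ctr <- degenerate_contrasts(dat, "value")
      ctr$metric <- metric
      ctr$singular <- TRUE
      ctr$moran_i <- NA_real_
      ctr$moran_p <- NA_real_
      return(ctr)
    }
    singular <- lme4::isSingular(fit)
    emm <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite")
    prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
    mor <- tryCatch(
      suppressWarnings(morans_i(resid(fit), inverse_distance_weights(dat$time))),
      error = function(e) NULL)
    data.frame(metric = metric, pair = prs$contrast,
               difference = prs$estimate, se = prs$SE, df = prs$df,
               t = prs$t.ratio, p_value = prs$p.value,
               moran_i = if (is.null(mor)) NA_real_ else mor$I,
               moran_p = if (is.null(mor)) NA_real_ else mor$p_value,
               singular = singular)
  })
  out <- do.call(rbind, res)
  out$scale <- scale
  out <- out[, c("metric", "scale", "pair", "difference", "se", "df", "t",
                 "p_value", "moran_i", "moran_p", "singular")]
  rownames(out) <- NULL
  class(out) <- c("thermal_contrasts", "data.frame")
  out
}

#' @export
print.thermal_contrasts <- function(x, ...) {
  cat(sprintf("Pairwise group contrasts (%s scale)\n",
              x$scale[1] %||% "?"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-6s %-28s %+0.2f +/- %.2f degC  t_%s = %.2f, p = %.3g%s\n",
                x$metric[i], x$pair[i], x$difference[i], x$se[i],
                ifelse(is.na(x$df[i]), "?", sprintf("%.1f", x$df[i])),
                x$t[i], x$p_value[i],
                ifelse(x$singular[i], " [singular]", "")))
  }
  invisible(x)
}
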