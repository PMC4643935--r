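# Configuration, orchestration and report assembly for the full pipeline:
# simulate -> qc -> metrics -> compare -> project.

#' Group labels for the probes of a study
#'
#' One group per meadow, except that partially grazed meadows (both
#' treatments present) contribute one group per treatment, e.g.
#' `Mulkey_grazed` and `Mulkey_ungrazed`.
#'
#' @param probes probe metadata with `probe_id`, `meadow`, `treatment`.
#' @return named character vector mapping `probe_id` to group label.
#' @export
probe_groups <- function(probes) {
  multi <- tapply(probes$treatment, probes$meadow,
                  function(v) length(unique(v)) > 1)
  g <- ifelse(multi[probes$meadow],
              paste(probes$meadow, probes$treatment, sep = "_"),
              probes$meadow)
  stats::setNames(as.character(g), probes$probe_id)
}

# Meadows holding both treatments (the partially grazed ones).
mixed_meadows <- function(probes) {
  multi <- tapply(probes$treatment, probes$meadow,
                  function(v) length(unique(v)) > 1)
  names(multi)[multi]
}

pipeline_defaults <- function() {
  list(seed = 1L,
       simulate = TRUE,
       input_dir = NULL,
       out_dir = NULL,
       weeks = c(24L, 31L),
       week_convention = "iso",
       years = c(2010L, 2011L, 2012L),
       completeness_frac = 0.75,
       window_days = 7L,
       min_days = 4L,
       align = "center",
       scales = "month",
       mode = "per_probe",
       ratio = 0.5,
       sd_mode = "total",
       pool_mulkey = TRUE,
       sim = list())
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list), applies documented
#' defaults, and reports *every* violated constraint at once rather than
#' failing on the first.
#'
#' @param config path to a YAML file, or a list of settings.
#' @return the completed configuration list; errors list all violations.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      stop(sprintf("unparseable config: %s", conditionMessage(e)),
           call. = FALSE)
    })
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("'config' must be a list or a file path", call. = FALSE)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  w <- cfg$weeks
  if (length(w) != 2 || any(!is.finite(w)) || any(w < 1 | w > 53)) {
    add("weeks must be two week numbers within 1..53")
  } else if (w[1] > w[2]) {
    add("first_week > last_week")
  }
  if (!cfg$week_convention %in% c("iso", "ordinal")) {
    add("week_convention must be 'iso' or 'ordinal'")
  }
  if (!is.numeric(cfg$ratio) || length(cfg$ratio) != 1 || cfg$ratio <= 0) {
    add("ratio must be positive")
  }
  if (!cfg$sd_mode %in% c("total", "residual")) {
    add("sd_mode must be 'total' or 'residual'")
  }
  if (!all(cfg$scales %in% c("week", "month", "year"))) {
    add("scales must be among week/month/year")
  }
  if (length(cfg$scales) == 0) add("scales must be non-empty")
  if (!cfg$mode %in% c("per_probe", "per_reach")) {
    add("mode must be 'per_probe' or 'per_reach'")
  }
  if (!is.numeric(cfg$completeness_frac) || cfg$completeness_frac < 0 ||
      cfg$completeness_frac > 1) {
    add("completeness_frac must lie in [0, 1]")
  }
  if (!cfg$align %in% c("center", "trailing")) {
    add("align must be 'center' or 'trailing'")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    add("seed must be a single integer")
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$input_dir)) {
    add("input_dir is required when simulate is false")
  }
  if (!is.null(cfg$scenarios)) {
    sc <- cfg$scenarios
    if (is.null(nrow(sc)) || !all(c("label", "delta_water") %in% names(sc))) {
      add("scenarios must be a table with label and delta_water")
    }
  }
  if (length(errs)) {
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"), call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate unless `simulate: false`, then
#' QC, metrics, grazing comparisons, and scenario projection), writing all
#' stage outputs plus `summary.txt` and `run.log` under `out_dir`.
#' Re-running with an identical configuration reproduces identical
#' machine-readable outputs.
#'
#' @param config configuration list or YAML path, see [validate_config()].
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param last_stage stop after this stage (`"simulate"`, `"qc"`,
#'   `"metrics"`, `"compare"` or `"project"`); default runs everything.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         last_stage = c("project", "simulate", "qc",
                                        "metrics", "compare")) {
  last_stage <- match.arg(last_stage)
  rank <- c(simulate = 1, qc = 2, metrics = 3, compare = 4, project = 5)
  last_rank <- rank[[last_stage]]
  cfg <- validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("[%s] meadowtherm %s pipeline start\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              as.character(packageVersion("meadowtherm"))),
      file = log_path)
  warnings_seen <- character()
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  logf("config: %s", paste(deparse(cfg[setdiff(names(cfg), "scenarios")]),
                           collapse = " "))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("stage %s done in %.2f s", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  weeks <- seq(cfg$weeks[1], cfg$weeks[2])
  study <- stage("simulate", {
    if (isTRUE(cfg$simulate)) {
      params <- do.call(sim_params, utils::modifyList(list(seed = cfg$seed),
                                                      cfg$sim))
      st <- build_study(params, weeks = weeks, years = cfg$years)
      st$willows <- simulate_willows(seed = cfg$seed)
      write_study(st, file.path(out_dir, "input"))
      write.csv(st$willows, file.path(out_dir, "input", "willows.csv"),
                row.names = FALSE)
      st
    } else {
      st <- read_study(cfg$input_dir, window = cfg$weeks, years = cfg$years)
      wpath <- file.path(cfg$input_dir, "willows.csv")
      if (file.exists(wpath)) {
        w <- read.csv(wpath)
        class(w) <- c("willow_survey", "data.frame")
        st$willows <- w
      }
      st
    }
  })

  if (last_rank < 2) {
    logf("pipeline stopped after stage %s", last_stage)
    return(invisible(list(config = cfg, study = study)))
  }
  qc <- stage("qc", {
    q <- qc_study(study, window = cfg$weeks, years = cfg$years,
                  convention = cfg$week_convention)
    write.csv(attr(q, "qc_table"), file.path(out_dir, "qc_report.csv"),
              row.names = FALSE)
    q
  })
  qct <- attr(qc, "qc_table")
  if (sum(qct$days_removed) > 0) {
    warnings_seen <- c(warnings_seen,
                       sprintf("QC removed %d probe-day(s) flagged out of water",
                               sum(qct$days_removed)))
  }

  if (last_rank < 3) {
    logf("pipeline stopped after stage %s", last_stage)
    return(invisible(list(config = cfg, study = study, qc = qc)))
  }
  metrics <- stage("metrics", {
    m <- study_metrics(qc, completeness_frac = cfg$completeness_frac,
                       window_days = cfg$window_days, min_days = cfg$min_days,
                       align = cfg$align)
    write.csv(m$daily, file.path(out_dir, "daily.csv"), row.names = FALSE)
    write.csv(m$weekly, file.path(out_dir, "weekly.csv"), row.names = FALSE)
    write.csv(m$season, file.path(out_dir, "season_maxima.csv"),
              row.names = FALSE)
    m
  })

  probes <- qc$probes
  groups <- probe_groups(probes)

  if (last_rank < 4) {
    logf("pipeline stopped after stage %s", last_stage)
    return(invisible(list(config = cfg, study = study, qc = qc,
                          metrics = metrics)))
  }
  cmp <- stage("compare", {
    sites <- site_summary(metrics$weekly, groups)
    write.csv(sites, file.path(out_dir, "site_summary.csv"), row.names = FALSE)
    contrasts <- do.call(rbind, lapply(cfg$scales, function(sc) {
      agg <- aggregate_metric(metrics$weekly, scale = sc, mode = cfg$mode,
                              groups = groups)
      compare_groups_lmm(agg)
    }))
    write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
    grads <- gradient_regression(metrics$season, probes)
    write.csv(grads, file.path(out_dir, "gradients.csv"), row.names = FALSE)
    veg <- NULL
    mixed <- mixed_meadows(probes)
    if (length(mixed) == 1) {
      sub <- probes[probes$meadow == mixed, ]
      tab <- table(sub$treatment, sub$vegetation)
      chi <- tryCatch(vegetation_type_test(tab), error = function(e) NULL)
      sun <- shade_logistic(binarize_solar(sub$solar_pct), sub$treatment)
      veg <- data.frame(meadow = mixed,
                        chi2 = chi$statistic %||% NA_real_,
                        chi2_df = chi$df %||% NA_real_,
                        chi2_p = chi$p_value %||% NA_real_,
                        sunny_grazed = unname(sun$proportions["grazed"]),
                        sunny_ungrazed = unname(sun$proportions["ungrazed"]),
                        shade_z = sun$z, shade_p = sun$p_value,
                        shade_method = sun$method)
      write.csv(veg, file.path(out_dir, "vegetation.csv"), row.names = FALSE)
    }
    willows <- NULL
    if (!is.null(study$willows)) {
      sp <- willow_spacing(study$willows)
      hh <- willow_heights(study$willows)
      willows <- merge(sp$summary, hh$summary, by = c("treatment", "n"))
      willows$spacing_F <- sp$comparison$F %||% NA_real_
      willows$spacing_p <- sp$comparison$p_value %||% NA_real_
      willows$height_F <- hh$comparison$F %||% NA_real_
      willows$height_p <- hh$comparison$p_value %||% NA_real_
      write.csv(willows, file.path(out_dir, "willows_summary.csv"),
                row.names = FALSE)
    }
    if (any(contrasts$singular)) {
      warnings_seen <- c(warnings_seen,
                         "singular mixed-model fit(s) in group contrasts")
    }
    list(sites = sites, contrasts = contrasts, gradients = grads,
         vegetation = veg, willows = willows)
  })

  if (last_rank < 5) {
    logf("pipeline stopped after stage %s", last_stage)
    return(invisible(list(config = cfg, study = study, qc = qc,
                          metrics = metrics, compare = cmp)))
  }
  proj <- stage("project", {
    dat <- max_avg_table(metrics$daily, metrics$weekly, probes)
    if (!cfg$pool_mulkey) {
      mixed <- mixed_meadows(probes)
      drop_ids <- probes$probe_id[probes$meadow %in% mixed &
                                    probes$treatment == "ungrazed"]
      dat <- dat[!dat$probe_id %in% drop_ids, ]
    }
    model <- fit_max_vs_avg(dat, sd_mode = cfg$sd_mode)
    scen <- if (!is.null(cfg$scenarios)) {
      as.data.frame(cfg$scenarios)
    } else {
      default_scenarios()
    }
    tab <- recurrence_table(model, scen)
    write.csv(tab, file.path(out_dir, "projections.csv"), row.names = FALSE)
    if (any(model$meadows$singular %||% FALSE)) {
      warnings_seen <- c(warnings_seen, "singular projection-model fit")
    }
    list(model = model, table = tab)
  })

  stage("summary", {
    path <- file.path(out_dir, "summary.txt")
    con <- file(path, "w")
    on.exit(close(con))
    sink(con)
    cat("meadowtherm pipeline summary\n")
    cat("============================\n\n")
    cat(sprintf("window: weeks %d-%d (%s), years %s; seed %d\n\n",
                cfg$weeks[1], cfg$weeks[2], cfg$week_convention,
                paste(cfg$years, collapse = ","), cfg$seed))
    cat("Site temperature summary (mean +/- sd over probe-days)\n")
    print(cmp$sites, row.names = FALSE)
    cat("\n")
    print(cmp$contrasts)
    cat("\n")
    print(cmp$gradients)
    cat("\n")
    if (!is.null(cmp$willows)) {
      cat("Willow survey (per treatment)\n")
      print(cmp$willows, row.names = FALSE)
      cat("\n")
    }
    print(proj$model)
    cat("\n")
    print(proj$table)
    if (length(warnings_seen)) {
      cat("\nWarnings\n--------\n")
      cat(paste("-", warnings_seen, collapse = "\n"), "\n")
    }
    sink()
    invisible(NULL)
  })
  logf("pipeline complete")
  invisible(list(config = cfg, study = study, qc = qc, metrics = metrics,
                 compare = cmp, projection = proj))
}
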