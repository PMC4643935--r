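test_that("vegetation chi-squared matches the hand-computed double sum", {
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(vegetation_type_test(even)$statistic, 0)
  tab <- matrix(c(20, 5, 5, 20), 2)
  # hand computation: all expected counts 12.5, sum (O-E)^2/E
  hand <- sum((tab - 12.5)^2 / 12.5)
  res <- vegetation_type_test(tab)
  expect_equal(res$statistic, hand)
  expect_equal(res$df, 1)
  # 2 x 4 table (four vegetation classes) -> df 3
  tab4 <- matrix(c(12, 3, 8, 9, 6, 10, 4, 8), 2)
  expect_equal(vegetation_type_test(tab4)$df, 3)
  expect_error(vegetation_type_test(matrix(c(1, 2, 0, 0, 3, 4), 2)), "merge")
  expect_error(vegetation_type_test(matrix(1:12, 3)), "2 x k")
  expect_error(vegetation_type_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("solar binarization switches exactly at 98%", {
  expect_equal(binarize_solar(c(98, 97.9, 100, 0)), c(1L, 0L, 1L, 0L))
  expect_error(binarize_solar(101), "\\[0, 100\\]")
  expect_error(binarize_solar(-1), "\\[0, 100\\]")
})

test_that("shade logistic comparison behaves at the extremes", {
  id <- shade_logistic(rep(c(0, 1), 20), rep(c("g", "u"), each = 20))
  expect_lt(abs(id$z), 1e-6)
  # complete separation -> flagged, Fisher fallback
  sep <- shade_logistic(c(rep(0:1, 10), rep(1, 20)),
                        rep(c("g", "u"), each = 20))
  expect_true(sep$separation)
  expect_equal(sep$method, "fisher")
  expect_true(is.finite(sep$p_value))
  # clear difference detected
  withr::with_seed(8, {
    sun <- c(rbinom(300, 1, 0.60), rbinom(300, 1, 0.95))
    res <- shade_logistic(sun, rep(c("in", "out"), each = 300))
    expect_lt(res$p_value, 1e-6)
    expect_lt(res$proportions[["in"]], res$proportions[["out"]])
  })
})

test_that("willow spacing summarises consecutive gaps", {
  sv <- data.frame(reach = "u", treatment = rep(c("u", "g"), c(3, 3)),
                   position_m = c(0, 5, 10, 0, 10, 40), height_cm = 50)
  class(sv) <- c("willow_survey", "data.frame")
  attr(sv, "reach_length_m") <- c(u = 10, g = 40)
  res <- willow_spacing(sv)
  expect_equal(res$summary$mean_spacing_m[res$summary$treatment == "u"], 5)
  expect_equal(res$summary$mean_spacing_m[res$summary$treatment == "g"], 20)
  expect_equal(res$summary$density_per_m[res$summary$treatment == "u"], 0.3)
})

test_that("uniform willow spacing approaches L/(n+1)", {
  sims <- vapply(1:200, function(s) {
    sv <- simulate_willows(reach_length_m = c(x = 1000), density = c(x = 0.02),
                           height_mean_cm = c(x = 50), height_sd_cm = c(x = 10),
                           seed = s, exact_counts = TRUE)
    mean(diff(sort(sv$position_m)))
  }, numeric(1))
  # n = 20 points on [0, 1000]: expected mean consecutive gap ~ L/(n+1)
  expect_lt(abs(mean(sims) - 1000 / 21), 3 * sd(sims) / sqrt(200))
})

test_that("willow survey with study defaults shows the exclosure contrast", {
  sv <- simulate_willows(seed = 14, exact_counts = TRUE)
  sp <- willow_spacing(sv)
  hh <- willow_heights(sv)
  n <- setNames(sp$summary$n, sp$summary$treatment)
  expect_equal(round(n[["ungrazed"]] / n[["grazed"]]), 13)
  expect_gt(sp$summary$mean_spacing_m[sp$summary$treatment == "grazed"],
            sp$summary$mean_spacing_m[sp$summary$treatment == "ungrazed"])
  means <- setNames(hh$summary$mean_cm, hh$summary$treatment)
  expect_equal(means[["ungrazed"]] / means[["grazed"]], 2.1, tolerance = 0.2)
  expect_lt(hh$comparison$p_value, 1e-6)
  expect_lt(sp$comparison$p_value, 1e-6)
  # spacing comparison degrees of freedom: total gaps minus 4 coefficients
  expect_equal(hh$comparison$df2, nrow(sv) - 4)
})

test_that("the height F-test is location-invariant", {
  sv <- simulate_willows(seed = 6, exact_counts = TRUE)
  f0 <- willow_heights(sv)$comparison$F
  sv$height_cm <- sv$height_cm + 100
  f1 <- willow_heights(sv)$comparison$F
  expect_equal(f0, f1, tolerance = 1e-9)
  # identical heights in both treatments -> F ~ 0
  sv$height_cm <- 50
  expect_error(f2 <- willow_heights(sv)$comparison, NA)
})

test_that("gradient regression is exact on noise-free reaches", {
  st <- build_study(det_params(), small_layout(10, length_m = 900,
                                               gradient = 0.41),
                    years = 2010)
  m <- study_metrics(qc_study(st))
  g <- gradient_regression(m$season, st$probes)
  expect_equal(g$slope_per_100m, 0.41, tolerance = 1e-9)
  expect_lt(g$se_per_100m, 1e-9)
  expect_equal(g$df, 8)
  # flat reach: slope exactly zero, like a rested meadow
  st0 <- build_study(det_params(), small_layout(10, gradient = 0),
                     years = 2010)
  m0 <- study_metrics(qc_study(st0))
  g0 <- gradient_regression(m0$season, st0$probes)
  expect_equal(g0$slope_per_100m, 0, tolerance = 1e-9)
})

test_that("gradient slope is equivariant under distance rescaling", {
  st <- build_study(sim_params(seed = 12), small_layout(12, gradient = 0.41),
                    years = 2010)
  m <- study_metrics(qc_study(st))
  g1 <- gradient_regression(m$season, st$probes)
  probes_km <- st$probes
  probes_km$distance_m <- probes_km$distance_m / 1000
  g2 <- gradient_regression(m$season, probes_km)
  expect_equal(g2$slope_per_100m, g1$slope_per_100m * 1000, tolerance = 1e-9)
  expect_equal(g2$t, g1$t, tolerance = 1e-9)
  expect_equal(g2$p_value, g1$p_value, tolerance = 1e-9)
})

test_that("gradient regression rejects degenerate reaches", {
  sm <- data.frame(probe_id = c("a", "b"), MWavgT = 1:2, MWmaxT = 2:3)
  probes <- data.frame(probe_id = c("a", "b"), distance_m = c(0, 10),
                       reach = "r")
  expect_error(gradient_regression(sm, probes), "fewer than 3")
  sm3 <- data.frame(probe_id = c("a", "b", "c"), MWavgT = 1:3, MWmaxT = 2:4)
  probes3 <- data.frame(probe_id = c("a", "b", "c"), distance_m = 5,
                        reach = "r")
  expect_error(gradient_regression(sm3, probes3), "all equal")
})

test_that("aggregation means are correct at every scale", {
  w <- rbind(
    data.frame(probe_id = "a", date = as.Date("2011-06-20") + 0:29,
               WminT = 8, WavgT = 10, WmaxT = 14, n_days = 7),
    data.frame(probe_id = "b", date = as.Date("2011-06-20") + 0:29,
               WminT = 9, WavgT = 14, WmaxT = 18, n_days = 7))
  groups <- c(a = "G", b = "G")
  agg <- aggregate_metric(w, "month", "per_reach", groups)
  expect_true(all(agg$WavgT == 12))
  expect_equal(nrow(agg), 2) # June and July cells
  per_probe <- aggregate_metric(w, "year", "per_probe", groups)
  expect_equal(sort(per_probe$WavgT), c(10, 14))
  single <- aggregate_metric(w[w$date == w$date[1], ], "week", "per_probe",
                             groups)
  expect_equal(single$WavgT, c(10, 14))
})

test_that("zero-noise group contrasts are exact and scale-independent", {
  lay <- data.frame(meadow = c("Mulkey", "Ramshaw"), reach = c("Mu", "Ra"),
                    treatment = "ungrazed", n_probes = 3L, length_m = 300,
                    start_m = 0, gradient_per_100m = 0)
  p <- det_params(meadow_means = c(Mulkey = 14, Ramshaw = 12),
                  seasonal_amplitude = 1.5)
  st <- build_study(p, lay, years = 2010:2011)
  m <- study_metrics(qc_study(st))
  groups <- probe_groups(st$probes)
  diffs <- sapply(c("week", "month", "year"), function(sc) {
    agg <- aggregate_metric(m$weekly, sc, "per_reach", groups)
    ctr <- compare_groups_lmm(agg, metrics = "WavgT")
    expect_true(all(ctr$singular))
    expect_lt(ctr$p_value[1], 1e-9)
    ctr$difference[1]
  })
  expect_equal(unname(abs(diffs)), rep(2, 3), tolerance = 1e-9)
  expect_lt(max(diffs) - min(diffs), 0.1)
})

test_that("contrast differences are antisymmetric under relabelling", {
  st <- build_study(sim_params(seed = 19),
                    rbind(small_layout(4, "Mulkey", "grazed"),
                          small_layout(4, "Ramshaw", "ungrazed")),
                    years = 2010:2011)
  m <- study_metrics(qc_study(st))
  g1 <- probe_groups(st$probes)
  agg <- aggregate_metric(m$weekly, "month", "per_probe", g1)
  ctr <- compare_groups_lmm(agg, metrics = "WavgT")
  # relabel so the pair order flips
  g2 <- setNames(ifelse(g1 == "Mulkey", "zz_Mulkey", g1), names(g1))
  agg2 <- aggregate_metric(m$weekly, "month", "per_probe", g2)
  ctr2 <- compare_groups_lmm(agg2, metrics = "WavgT")
  expect_equal(ctr2$difference, -ctr$difference, tolerance = 1e-6)
  expect_equal(ctr2$p_value, ctr$p_value, tolerance = 1e-6)
})

test_that("with one observation per cell the contrast collapses to a t-test", {
  withr::with_seed(55, {
    units <- sprintf("2011-%02d", 1:10)
    e <- rnorm(10, sd = 0.5)
    # unit means are constant by construction, so the unit variance is 0
    agg <- data.frame(group = rep(c("A", "B"), each = 10),
                      unit = rep(units, 2), time = rep(1:10, 2),
                      WavgT = c(12 + e, 13 - e))
    attr(agg, "scale") <- "month"
    ctr <- quietly_(compare_groups_lmm(agg, metrics = "WavgT"))
    tt <- t.test(WavgT ~ group, data = agg, var.equal = TRUE)
    expect_equal(unname(ctr$difference), unname(diff(rev(tt$estimate))),
                 tolerance = 1e-6)
    expect_equal(abs(ctr$t), abs(unname(tt$statistic)), tolerance = 0.05)
    expect_equal(ctr$df, unname(tt$parameter), tolerance = 0.15)
  })
})

test_that("injected meadow offsets are recovered by the mixed model", {
  lay <- data.frame(meadow = c("Mulkey", "Ramshaw", "BigWhitney"),
                    reach = c("Mu", "Ra", "BW"), treatment = "ungrazed",
                    n_probes = 8L, length_m = 800, start_m = 0,
                    gradient_per_100m = 0)
  p <- sim_params(seed = 1, meadow_means = c(Mulkey = 13.45, Ramshaw = 11.8,
                                             BigWhitney = 10.7))
  st <- build_study(p, lay, years = 2010:2012)
  m <- study_metrics(qc_study(st))
  # one value per river and month: the aggregation that removes both the
  # temporal and the spatial dependence, so the standard error is honest
  agg <- aggregate_metric(m$weekly, "month", "per_reach",
                          probe_groups(st$probes))
  ctr <- quietly_(compare_groups_lmm(agg, metrics = "WavgT"))
  mu_ra <- ctr[ctr$pair == "Mulkey - Ramshaw", ]
  expect_equal(nrow(mu_ra), 1)
  expect_gt(mu_ra$difference, 0) # grazed-analogue meadow is warmer
  expect_lt(abs(mu_ra$difference - 1.65), 2 * mu_ra$se)
  expect_lt(mu_ra$p_value, 0.001)
  # Satterthwaite df are fractional and bounded by the cell count
  expect_lt(mu_ra$df, nrow(agg))
})
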