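test_that("build_study returns the configured probe network", {
  study <- build_study(det_params(), years = 2010)
  expect_s3_class(study, "therm_study")
  expect_equal(nrow(study$probes), 81) # 30 + 30 + 21
  expect_length(study$series, 81)
  expect_setequal(study$probes$probe_id, names(study$series))
  # one upstream (distance 0) probe per reach
  d0 <- tapply(study$probes$distance_m, study$probes$reach,
               function(d) sum(d == 0))
  expect_true(all(d0 == 1))
  expect_true(all(study$probes$solar_pct >= 0 & study$probes$solar_pct <= 100))
})

test_that("simulation is deterministic given the seed", {
  p <- sim_params(seed = 42)
  lay <- small_layout(4)
  s1 <- build_study(p, lay, years = 2011)
  s2 <- build_study(p, lay, years = 2011)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$series, s2$series)
  s3 <- build_study(sim_params(seed = 43), lay, years = 2011)
  expect_false(identical(s1$series[[1]]$temp_c, s3$series[[1]]$temp_c))
})

test_that("adding a probe does not perturb existing probes' series", {
  p <- sim_params(seed = 9)
  s_small <- build_study(p, small_layout(4), years = 2011)
  s_big <- build_study(p, small_layout(6), years = 2011)
  # probes share ids and positions only partly; compare via common metadata
  m1 <- s_small$probes[1, ]
  shared <- simulate_series(m1, p, 24:31, 2011)
  expect_identical(shared$temp_c, s_small$series[[m1$probe_id]]$temp_c)
})

test_that("zero-noise series is the exact deterministic curve", {
  p <- det_params()
  meta <- list(probe_id = "x", meadow = "Mulkey", treatment = "grazed",
               distance_m = 0, solar_pct = 99)
  s <- simulate_series(meta, p, 24:31, 2010)
  expect_equal(length(s), 8 * 7 * 48)
  d <- daily_summaries(s)
  # flat season, no noise: every day identical, range = 2 * amplitude
  expect_equal(var(d$DavgT), 0, tolerance = 1e-12)
  expect_equal(unique(round(d$DmaxT - d$DminT, 10)),
               2 * p$diel_amplitude_sunny)
  # daily mean equals meadow mean (distance 0, no reach length -> no centring)
  expect_equal(d$DavgT[1], p$meadow_means[["Mulkey"]], tolerance = 1e-9)
})

test_that("downstream gradient appears exactly in the daily maxima", {
  p <- det_params()
  m1 <- list(probe_id = "a", meadow = "Mulkey", treatment = "grazed",
             distance_m = 0, solar_pct = 99)
  m2 <- modifyList(m1, list(probe_id = "b", distance_m = 100))
  d1 <- daily_summaries(simulate_series(m1, p, 24:31, 2010))
  d2 <- daily_summaries(simulate_series(m2, p, 24:31, 2010))
  expect_equal(max(d2$DmaxT) - max(d1$DmaxT), 0.41, tolerance = 1e-9)
  # gradient also holds day by day
  expect_equal(d2$DmaxT - d1$DmaxT, rep(0.41, nrow(d1)), tolerance = 1e-9)
})

test_that("solar exposure picks the diel amplitude at the 98% threshold", {
  p <- det_params(diel_amplitude_sunny = 5, diel_amplitude_shaded = 3)
  m_shade <- list(probe_id = "s", meadow = "Mulkey", treatment = "grazed",
                  distance_m = 0, solar_pct = 97)
  m_sun <- modifyList(m_shade, list(probe_id = "u", solar_pct = 99))
  rng <- function(m) {
    d <- daily_summaries(simulate_series(m, p, 25, 2010))
    unique(round(d$DmaxT - d$DminT, 9))
  }
  expect_equal(rng(m_shade), 6)
  expect_equal(rng(m_sun), 10)
})

test_that("probe identity alone does not change the deterministic component", {
  p <- det_params()
  m1 <- list(probe_id = "a", meadow = "Ramshaw", treatment = "ungrazed",
             distance_m = 50, solar_pct = 99)
  m2 <- modifyList(m1, list(probe_id = "zz"))
  s1 <- simulate_series(m1, p, 24:26, 2010)
  s2 <- simulate_series(m2, p, 24:26, 2010)
  expect_equal(s1$temp_c, s2$temp_c, tolerance = 1e-12)
})

test_that("build_study rejects degenerate layouts", {
  expect_error(build_study(det_params(), weeks = integer(0)), "empty week")
  lay <- small_layout(1)
  expect_error(build_study(det_params(), lay), "at least 2 probes")
  lay2 <- small_layout(4)
  lay2$length_m <- 0
  expect_error(build_study(det_params(), lay2), "positive")
  lay3 <- rbind(small_layout(4), small_layout(4))
  expect_error(build_study(det_params(), lay3), "duplicate reach")
})

test_that("willow survey honours exact counts and height truncation", {
  sv <- simulate_willows(exact_counts = TRUE, seed = 3)
  counts <- table(sv$treatment)
  expect_equal(unname(counts[["ungrazed"]]), 980)
  expect_equal(unname(counts[["grazed"]]), 75)
  expect_true(all(sv$height_cm >= 1))
  expect_true(all(sv$position_m >= 0))
  expect_true(all(sv$position_m[sv$treatment == "grazed"] <= 900))
  # zero spread -> all heights at the mean
  sv0 <- simulate_willows(height_sd_cm = c(ungrazed = 0, grazed = 0),
                          exact_counts = TRUE, seed = 1)
  expect_setequal(unique(sv0$height_cm), c(92, 43))
  expect_error(simulate_willows(density = c(ungrazed = 0, grazed = 1)),
               "positive")
})

test_that("Poisson willow counts have the right mean", {
  counts <- vapply(1:1000, function(s) {
    nrow(simulate_willows(reach_length_m = c(x = 100), density = c(x = 0.01),
                          height_mean_cm = c(x = 50), height_sd_cm = c(x = 10),
                          seed = s))
  }, numeric(1))
  # Poisson(1): mean 1, se of the mean over 1000 draws = 1/sqrt(1000)
  expect_lt(abs(mean(counts) - 1), 3 / sqrt(1000))
})

test_that("out-of-water injection corrupts exactly the listed days", {
  p <- det_params()
  meta <- list(probe_id = "x", meadow = "Mulkey", treatment = "grazed",
               distance_m = 0, solar_pct = 99)
  s <- simulate_series(meta, p, 24:25, 2010)
  expect_identical(inject_out_of_water(s, as.Date(character())), s)
  days <- as.Date(c("2010-06-15", "2010-06-22"))
  bad <- inject_out_of_water(s, days, seed = 5)
  expect_setequal(format(bad$flags$date), format(days))
  clean_rng <- max(tapply(s$temp_c, day_of(s$time),
                          function(v) diff(range(v))))
  for (d in as.list(days)) {
    idx <- day_of(bad$time) == d
    expect_gt(diff(range(bad$temp_c[idx])), 2 * clean_rng)
  }
  # untouched days identical
  ok <- !(day_of(s$time) %in% days)
  expect_equal(bad$temp_c[ok], s$temp_c[ok])
  expect_error(inject_out_of_water(s, as.Date("2019-01-01")), "present")
})

test_that("same-day residual correlation decays with distance", {
  lay <- small_layout(12, length_m = 1200, gradient = 0)
  p <- sim_params(seed = 21, spatial_range = 150, sample_noise_sd = 0,
                  seasonal_amplitude = 0)
  st <- build_study(p, lay, years = 2010)
  daily <- do.call(rbind, lapply(st$series, daily_summaries))
  wide <- do.call(cbind, lapply(split(daily$DavgT, daily$probe_id), identity))
  wide <- wide[, st$probes$probe_id]
  resmat <- scale(wide, scale = FALSE)
  dd <- abs(outer(st$probes$distance_m, st$probes$distance_m, "-"))
  cc <- cor(resmat)
  bins <- cut(dd[upper.tri(dd)], c(0, 200, 500, 1200))
  bycor <- tapply(cc[upper.tri(cc)], bins, mean)
  expect_true(all(diff(bycor) < 0))
})
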