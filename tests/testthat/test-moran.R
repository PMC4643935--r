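test_that("inverse-distance weights follow the reciprocal rule", {
  w <- inverse_distance_weights(c(0, 1, 2))
  expect_equal(unclass(w), matrix(c(0, 1, 0.5, 1, 0, 1, 0.5, 1, 0), 3),
               ignore_attr = TRUE)
  # homogeneity: doubling distances halves the weights
  w2 <- inverse_distance_weights(c(0, 2, 4))
  expect_equal(unclass(w2), unclass(w) / 2, ignore_attr = TRUE)
})

test_that("coincident points are floored, fully coincident rejected", {
  expect_warning(w <- inverse_distance_weights(c(0, 0, 1, 3)), "coincident")
  expect_true(all(is.finite(w)))
  expect_equal(w[1, 2], 1 / 0.5) # half the smallest positive distance
  expect_error(inverse_distance_weights(c(2, 2, 2)), "coincident")
  expect_error(inverse_distance_weights(c(1, 2)), "at least 3")
})

test_that("great-circle weights scale with metric distance", {
  # ~1.57 km and ~3.14 km apart along a meridian
  pts <- data.frame(lon = c(-118.2, -118.2, -118.2),
                    lat = 36.4 + c(0, 1, 2) * 0.0141)
  w <- inverse_distance_weights(pts)
  expect_equal(w[1, 2] / w[1, 3], 2, tolerance = 1e-6)
})

test_that("Moran's I equals the explicit double sum", {
  withr::with_seed(77, {
    for (k in 1:25) {
      n <- sample(5:15, 1)
      pos <- sort(runif(n, 0, 100))
      vals <- rnorm(n)
      w <- inverse_distance_weights(pos)
      m <- morans_i(vals, w)
      expect_equal(m$I, naive_moran(vals, unclass(w)), tolerance = 1e-12)
      expect_equal(m$expected, -1 / (n - 1), tolerance = 1e-15)
    }
  })
})

test_that("Moran's I ranks spatial arrangements correctly", {
  w <- inverse_distance_weights(c(0, 1, 2, 3))
  blocky <- morans_i(c(1, 1, -1, -1), w) # like values adjacent
  altern <- morans_i(c(1, -1, 1, -1), w) # alternating
  expect_equal(blocky$I, naive_moran(c(1, 1, -1, -1), unclass(w)),
               tolerance = 1e-12)
  expect_equal(altern$I, naive_moran(c(1, -1, 1, -1), unclass(w)),
               tolerance = 1e-12)
  # alternation is strongly negative; adjacent like values are far less so
  expect_lt(altern$I, blocky$I)
  expect_lt(altern$I, altern$expected)
  # smoothly trended values give positive autocorrelation
  trend <- morans_i(c(1, 2, 3, 4), w)
  expect_gt(trend$I, trend$expected)
})

test_that("Moran's I matches an independent reference implementation", {
  skip_if_not_installed("ape")
  withr::with_seed(13, {
    for (k in 1:10) {
      n <- 12
      pos <- sort(runif(n, 0, 50))
      vals <- rnorm(n, sd = 2)
      w <- unclass(inverse_distance_weights(pos))
      # the reference implementation row-normalizes its weights internally;
      # hand it the raw matrix and ours the row-normalized one
      ours <- morans_i(vals, w / rowSums(w))
      ref <- ape::Moran.I(vals, w)
      expect_equal(ours$I, ref$observed, tolerance = 1e-10)
      expect_equal(ours$expected, ref$expected, tolerance = 1e-10)
      expect_equal(ours$sd, ref$sd, tolerance = 1e-8)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
    }
  })
})

test_that("Moran's I is affine- and weight-scale-invariant", {
  withr::with_seed(5, {
    vals <- rnorm(10)
    w <- inverse_distance_weights(sort(runif(10, 0, 10)))
    base <- morans_i(vals, w)
    aff <- morans_i(-3 * vals + 7, w)
    expect_equal(aff$I, base$I, tolerance = 1e-12)
    expect_equal(aff$p_value, base$p_value, tolerance = 1e-12)
    scaled <- morans_i(vals, unclass(w) * 42)
    expect_equal(scaled$I, base$I, tolerance = 1e-12)
  })
  expect_error(morans_i(rep(1, 5), inverse_distance_weights(1:5)),
               "constant")
})

test_that("mean of Moran's I over permutations sits at -1/(n-1)", {
  withr::with_seed(31, {
    n <- 8
    w <- unclass(inverse_distance_weights(sort(runif(n, 0, 10))))
    vals <- rnorm(n)
    sims <- vapply(1:1000, function(k) {
      v <- sample(vals)
      z <- v - mean(v)
      (n / sum(w)) * c(z %*% w %*% z) / sum(z^2)
    }, numeric(1))
    expect_lt(abs(mean(sims) - (-1 / (n - 1))), 3 * sd(sims) / sqrt(1000))
  })
})

test_that("permutation p-value agrees broadly with the normal one", {
  withr::with_seed(99, {
    pos <- sort(runif(30, 0, 30))
    # smooth long-wave pattern: strong local similarity
    vals <- sin(pos / 30 * 2 * pi) + rnorm(30, sd = 0.1)
    w <- inverse_distance_weights(pos)
    pn <- morans_i(vals, w)$p_value
    pp <- morans_i(vals, w, method = "permutation", nperm = 999)$p_value
    expect_lt(pn, 0.05)
    expect_lt(pp, 0.05)
  })
})

test_that("lag-1 autoregression recovers persistence", {
  x <- withr::with_seed(11, {
    as.numeric(stats::filter(rnorm(500, 0, sqrt(1 - 0.64)), 0.8, "recursive"))
  })
  fit <- lag1_autoregression(x)
  expect_gt(fit$slope, 0.7)
  expect_lt(fit$slope, 0.9)
  # exact linear ramp: slope 1
  ramp <- suppressWarnings(lag1_autoregression(as.numeric(1:20)))
  expect_equal(ramp$slope, 1, tolerance = 1e-10)
  expect_error(lag1_autoregression(c(1, 2, 3)), "at least 4")
})

test_that("lag-1 autoregression is null-calibrated on white noise", {
  hits <- withr::with_seed(7, {
    vapply(1:50, function(k) {
      f <- lag1_autoregression(rnorm(500))
      abs(f$slope) < 0.1 && f$p_value > 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("adjusted model recovers a pure treatment shift", {
  withr::with_seed(23, {
    n <- 60
    lon <- runif(n, -118.3, -118.1)
    lat <- runif(n, 36.3, 36.5)
    grp <- rep(c("a", "b"), each = n / 2)
    y <- 2 * (grp == "b") + rnorm(n, sd = 0.1)
    fit <- autoregressive_adjusted_model(y, grp, data.frame(lon = lon, lat = lat))
    expect_equal(unname(fit$coefficients["groupb"]), 2, tolerance = 0.1)
    expect_lt(fit$p_value, 1e-6)
    expect_equal(fit$df1, 1)
    expect_equal(fit$df2, n - 6)
  })
})

test_that("adjusted model is calibrated under a quadratic spatial null", {
  ps <- withr::with_seed(37, {
    vapply(1:20, function(k) {
      n <- 50
      lat <- runif(n, 0, 1)
      lon <- runif(n, 0, 1)
      grp <- rep(c("a", "b"), length.out = n)
      y <- 3 * (lat - 0.5)^2 + rnorm(n, sd = 0.2)
      autoregressive_adjusted_model(y, grp,
                                    data.frame(lon = lon, lat = lat))$p_value
    }, numeric(1))
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("coordinate adjustment shrinks residual Moran's I", {
  withr::with_seed(41, {
    n <- 40
    pos <- sort(runif(n, 0, 100))
    grp <- rep(c("a", "b"), length.out = n)
    y <- 0.05 * pos + rnorm(n, sd = 0.3) # strong linear trend in space
    unadj <- lm(y ~ grp)
    m0 <- morans_i(resid(unadj), inverse_distance_weights(pos))
    fit <- autoregressive_adjusted_model(y, grp, pos)
    expect_lt(abs(fit$moran$I), abs(m0$I))
  })
})

test_that("rank-deficient adjusted models are named, not silent", {
  n <- 20
  coords <- data.frame(lon = rep(1, n), lat = runif(n))
  expect_error(
    autoregressive_adjusted_model(rnorm(n), rep(c("a", "b"), n / 2), coords),
    "collinear")
})
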