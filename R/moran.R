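# Moran's I autocorrelation diagnostics and autoregression-adjusted models.
#
# Moran's I on model residuals is the package's standard check that a fit
# has not left structured spatial (or temporal) correlation behind:
#   I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
# with expectation -1/(n-1) under the randomization null.

#' Inverse-distance weight matrix
#'
#' Builds the weight matrix `w_ij = 1 / d_ij` used by [morans_i()].
#' Distances are great-circle (sphere of mean radius 6371 km) when `x` has
#' `lon`/`lat` columns, and absolute differences when `x` is a numeric
#' vector (positions along a transect, or times in days/weeks/months).
#' Coincident points have their distance floored at half the smallest
#' positive distance, with a warning.
#'
#' @param x numeric vector of 1-D positions/times, or a matrix/data frame
#'   with columns `lon` and `lat` in decimal degrees.
#' @return an `n x n` matrix of class `weight_matrix` with zero diagonal;
#'   the distance rule is recorded in attribute `dist_rule`.
#' @export
inverse_distance_weights <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.data.frame(x)
    if (!all(c("lon", "lat") %in% names(x))) {
      stop("matrix input needs 'lon' and 'lat' columns", call. = FALSE)
    }
    n <- nrow(x)
    if (n < 3) stop("need at least 3 points", call. = FALSE)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      d[i, (i + 1):n] <- geosphere::distHaversine(
        c(x$lon[i], x$lat[i]),
        cbind(x$lon[(i + 1):n], x$lat[(i + 1):n]), r = 6371000)
    }
    d <- d + t(d)
    rule <- "great-circle (m)"
  } else {
    x <- as.numeric(x)
    n <- length(x)
    if (n < 3) stop("need at least 3 points", call. = FALSE)
    d <- abs(outer(x, x, "-"))
    rule <- "absolute difference"
  }
  off <- d[upper.tri(d)]
  if (all(off == 0)) stop("all points are coincident", call. = FALSE)
  if (any(off == 0)) {
    floor_d <- min(off[off > 0]) / 2
    warning(sprintf("%d coincident pair(s); distance floored at %g",
                    sum(off == 0), floor_d))
    d[d == 0] <- floor_d
  }
  w <- 1 / d
  diag(w) <- 0
  structure(w, dist_rule = rule, class = c("weight_matrix", "matrix", "array"))
}

#' Moran's I autocorrelation coefficient
#'
#' Computes Moran's I for `values` under the weight matrix, its null
#' expectation `-1/(n-1)`, and a two-sided p-value either from the normal
#' approximation under the randomization assumption (default) or from a
#' seeded permutation test.
#'
#' @param values numeric vector (typically model residuals); must not be
#'   constant.
#' @param weights an `n x n` nonnegative weight matrix with zero diagonal,
#'   e.g. from [inverse_distance_weights()].
#' @param method `"normal"` or `"permutation"`.
#' @param nperm number of permutations when `method = "permutation"`.
#' @param seed seed for the permutation draw.
#' @return object of class `moran_result`: list with `I`, `expected`, `sd`,
#'   `p_value`, `n`, `method`.
#' @export
morans_i <- function(values, weights, method = c("normal", "permutation"),
                     nperm = 999, seed = 1L) {
  method <- match.arg(method)
  w <- unclass(weights)
  n <- length(values)
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n) {
    stop("'weights' must be an n x n matrix matching 'values'", call. = FALSE)
  }
  if (any(diag(w) != 0)) stop("weight matrix must have zero diagonal", call. = FALSE)
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("constant residuals: Moran's I undefined", call. = FALSE)
  s0 <- sum(w)
  obs_i <- function(zz) (n / s0) * as.numeric(zz %*% w %*% zz) / sum(zz^2)
  I <- obs_i(z)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / m2^2
  e_i2 <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
             b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2)
  sd_i <- sqrt(max(e_i2 - e_i^2, 0))
  if (method == "normal") {
    p <- 2 * pnorm(-abs((I - e_i) / sd_i))
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(nperm), function(k) obs_i(sample(z)), numeric(1))
    })
    p <- (1 + sum(abs(perm - e_i) >= abs(I - e_i))) / (nperm + 1)
  }
  structure(list(I = I, expected = e_i, sd = sd_i, p_value = p, n = n,
                 method = method),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f +/- %.4f (expected %.4f), p = %.3g [%s]\n",
              x$I, x$sd, x$expected, x$p_value, x$method))
  invisible(x)
}

#' Lag-1 autoregression of an aggregated metric series
#'
#' Ordinary regression of `x[t+1]` on `x[t]`; the slope estimates the lag-1
#' autocorrelation of the aggregated series.
#'
#' @param x numeric vector, at least 4 time points, in time order.
#' @return list with `slope`, `se`, `p_value`, `n`.
#' @export
lag1_autoregression <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 time points", call. = FALSE)
  fit <- lm(x[-1] ~ x[-n])
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       p_value = unname(sm[2, 4]), n = n)
}

#' Group comparison adjusted for polynomial spatial trend
#'
#' Linear model of a response on a two-level grouping plus the coordinates
#' and their squares, used when residual spatial autocorrelation would
#' otherwise inflate the group test. Reports the group F-test and Moran's I
#' of the residuals.
#'
#' @param response numeric vector.
#' @param group factor-like with the treatment labels.
#' @param coords numeric vector (1-D transect position) or data frame with
#'   `lon`/`lat`; quadratic terms of every coordinate are included.
#' @return object of class `adjusted_fit`: list with `coefficients`,
#'   `F`, `df1`, `df2`, `p_value`, `moran`, `fit`.
#' @export
autoregressive_adjusted_model <- function(response, group, coords) {
  n <- length(response)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  group <- factor(group)
  if (is.data.frame(coords) || is.matrix(coords)) {
    coords <- as.data.frame(coords)
    dat <- data.frame(y = response, group = group,
                      lon = coords$lon, lat = coords$lat)
    full <- y ~ group + lon + lat + I(lon^2) + I(lat^2)
    red <- y ~ lon + lat + I(lon^2) + I(lat^2)
  } else {
    dat <- data.frame(y = response, group = group, pos = as.numeric(coords))
    full <- y ~ group + pos + I(pos^2)
    red <- y ~ pos + I(pos^2)
  }
  fit <- lm(full, data = dat)
  alias <- is.na(coef(fit))
  if (any(alias)) {
    stop(sprintf("rank-deficient model; collinear term(s): %s",
                 paste(names(coef(fit))[alias], collapse = ", ")),
         call. = FALSE)
  }
  cmp <- anova(lm(red, data = dat), fit)
  mor <- tryCatch(
    morans_i(resid(fit),
             suppressWarnings(inverse_distance_weights(
               if (is.data.frame(coords)) coords else as.numeric(coords)))),
    error = function(e) NULL)
  structure(list(coefficients = coef(fit),
                 F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
                 p_value = cmp$`Pr(>F)`[2], moran = mor, fit = fit),
            class = "adjusted_fit")
}

#' @export
print.adjusted_fit <- function(x, ...) {
  cat(sprintf("Spatially adjusted comparison: F_%d,%d = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p_value))
  if (!is.null(x$moran)) {
    cat("  residual "); print(x$moran)
  }
  invisible(x)
}
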