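#' Simulation parameters for the synthetic logger network
#'
#' Bundles the generative parameters of the synthetic study. The generator
#' builds, for every probe, a deterministic daily mean (meadow baseline +
#' along-stream gradient + summer half-sine), adds a spatially correlated
#' AR(1) daily anomaly, and wraps a diel cosine around each daily mean whose
#' amplitude grows with the running weekly median temperature, so that the
#' daily maximum responds to the weekly average with slope
#' `max_vs_avg_slope`.
#'
#' The along-stream gradient is expressed on the scale of the *daily maximum*
#' (the scale on which downstream warming is usually reported); internally
#' the daily-mean gradient is `gradient / max_vs_avg_slope` and is centred at
#' the reach midpoint so that reach means are not shifted by the gradient.
#'
#' @param meadow_means named numeric, baseline summer mean water temperature
#'   per meadow (degC). The seasonal term is centred over the default summer
#'   window, so these are approximately the expected window means of WavgT.
#' @param diel_amplitude_sunny,diel_amplitude_shaded base half-range of the
#'   diel cosine (degC) for probes with solar exposure >= 98% and < 98%
#'   respectively; `diel_amplitude_shaded <= diel_amplitude_sunny`.
#' @param seasonal_amplitude degC amplitude of the summer half-sine.
#' @param seasonal_peak_week week of year at which the seasonal term peaks.
#' @param gradient_per_100m named numeric, degC per 100 m change in daily
#'   maximum temperature from upstream to downstream, by treatment
#'   (`grazed`, `ungrazed`); a layout may override per reach.
#' @param ar1_phi day-to-day persistence of the daily anomaly, in `[0, 1)`.
#' @param noise_sd stationary standard deviation (degC) of the daily anomaly.
#' @param sample_noise_sd within-day record-level noise sd (degC); default
#'   `noise_sd / 5` so that `noise_sd = 0` yields a fully deterministic study.
#' @param spatial_range e-folding distance (m) of the along-stream
#'   correlation of the daily anomaly between probes.
#' @param sampling_interval logger sampling interval in minutes, 20 or 30.
#' @param max_vs_avg_slope dimensionless response of daily maximum to weekly
#'   average temperature (1 = fixed diel amplitude); a scalar, or a named
#'   vector with one slope per meadow.
#' @param t_ref reference temperature (degC) around which the diel amplitude
#'   amplification is anchored.
#' @param min_amplitude floor (degC) for the diel amplitude.
#' @param shading_mean_effect optional shift (degC) of the daily *mean* for
#'   shaded probes; 0 by default (shading acts on the diel amplitude only).
#' @param seed integer root seed; all per-probe and per-meadow streams are
#'   derived from it by stable hashing.
#' @return an object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(noise_sd = 0, max_vs_avg_slope = 1)
#' p$meadow_means
#' @export
sim_params <- function(meadow_means = c(Mulkey = 13.1, Ramshaw = 11.8,
                                        BigWhitney = 10.7),
                       diel_amplitude_sunny = 3.5,
                       diel_amplitude_shaded = 2.0,
                       seasonal_amplitude = 2.0,
                       seasonal_peak_week = 28,
                       gradient_per_100m = c(grazed = 0.41, ungrazed = -0.25),
                       ar1_phi = 0.6,
                       noise_sd = 0.5,
                       sample_noise_sd = NULL,
                       spatial_range = 200,
                       sampling_interval = 30,
                       max_vs_avg_slope = 1.74,
                       t_ref = 10,
                       min_amplitude = 0.2,
                       shading_mean_effect = 0,
                       seed = 1L) {
  if (is.null(names(meadow_means)) || any(names(meadow_means) == "")) {
    stop("'meadow_means' must be a named numeric vector", call. = FALSE)
  }
  assert_scalar_number(ar1_phi, "ar1_phi", 0, 1 - 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(spatial_range, "spatial_range", 0)
  assert_scalar_number(diel_amplitude_sunny, "diel_amplitude_sunny", 0)
  assert_scalar_number(diel_amplitude_shaded, "diel_amplitude_shaded", 0)
  if (diel_amplitude_shaded > diel_amplitude_sunny) {
    stop("'diel_amplitude_shaded' must not exceed 'diel_amplitude_sunny'",
         call. = FALSE)
  }
  if (!sampling_interval %in% c(20, 30)) {
    stop("'sampling_interval' must be 20 or 30 minutes", call. = FALSE)
  }
  if (!is.numeric(max_vs_avg_slope) || any(max_vs_avg_slope <= 0) ||
      (length(max_vs_avg_slope) > 1 && is.null(names(max_vs_avg_slope)))) {
    stop("'max_vs_avg_slope' must be a positive scalar or named by meadow",
         call. = FALSE)
  }
  assert_scalar_number(seed, "seed")
  if (is.null(sample_noise_sd)) sample_noise_sd <- noise_sd / 5
  assert_scalar_number(sample_noise_sd, "sample_noise_sd", 0)
  if (is.null(names(gradient_per_100m))) {
    stop("'gradient_per_100m' must be named by treatment", call. = FALSE)
  }
  p <- list(meadow_means = meadow_means,
            diel_amplitude_sunny = diel_amplitude_sunny,
            diel_amplitude_shaded = diel_amplitude_shaded,
            seasonal_amplitude = seasonal_amplitude,
            seasonal_peak_week = seasonal_peak_week,
            gradient_per_100m = gradient_per_100m,
            ar1_phi = ar1_phi,
            noise_sd = noise_sd,
            sample_noise_sd = sample_noise_sd,
            spatial_range = spatial_range,
            sampling_interval = sampling_interval,
            max_vs_avg_slope = max_vs_avg_slope,
            t_ref = t_ref,
            min_amplitude = min_amplitude,
            shading_mean_effect = shading_mean_effect,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic study parameters\n")
  cat("  meadow means (degC):",
      paste(sprintf("%s=%.1f", names(x$meadow_means), x$meadow_means),
            collapse = ", "), "\n")
  cat(sprintf("  diel amplitude sunny/shaded: %.1f / %.1f degC\n",
              x$diel_amplitude_sunny, x$diel_amplitude_shaded))
  cat(sprintf("  daily anomaly: AR(1) phi=%.2f, sd=%.2f degC, range=%.0f m\n",
              x$ar1_phi, x$noise_sd, x$spatial_range))
  cat(sprintf("  max-vs-avg slope: %.2f; sampling every %d min; seed %d\n",
              x$max_vs_avg_slope, x$sampling_interval, x$seed))
  invisible(x)
}
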