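#' Simulate one season of daily weather for a zone
#'
#' Daily mean temperature follows a seasonal sinusoid (minimum at season
#' start, peak at mid-season) plus Gaussian noise. Rainfall is an
#' intermittent gamma process: wet days are drawn with a seasonally varying
#' probability (winter-wet for Mediterranean-type zones, uniform for the
#' temperate zone) and wet-day amounts from a gamma distribution; amounts are
#' rescaled so the annual total equals a uniform draw from the zone's annual
#' rainfall interval, which guarantees the zone's annual-total contract for
#' every seed. Relative humidity is a wet-day-elevated base with noise,
#' clipped to [20, 100].
#'
#' All vectors are season-relative: day 1 is the zone's season start.
#'
#' @param zone A \code{\link{zone_preset}} (or a list with the same fields).
#' @param year_seed Integer seed; identical seeds give identical output.
#' @return List with numeric 365-vectors \code{daily_temp} (deg C),
#'   \code{daily_rain} (mm, non-negative) and \code{daily_rh} (percent).
#' @export
simulate_weather <- function(zone, year_seed) {
  if (is.character(zone)) zone <- zone_preset(zone)
  if (is.null(zone$annual_rainfall_range) || is.null(zone$temp_mean)) {
    vp_stop("invalid zone preset")
  }
  set.seed(as.integer(year_seed))
  d <- seq_len(365)

  temp <- zone$temp_mean -
    zone$temp_amplitude * cos(2 * pi * (d - 1) / 365) +
    stats::rnorm(365, sd = zone$noise_sd)

  # wet-day probability: winter-wet zones concentrate rain at the season
  # edges (local winter), temperate rain is evenly spread
  if (isTRUE(zone$wet_season_winter)) {
    p_wet <- 0.12 + 0.24 * (1 + cos(2 * pi * (d - 1) / 365)) / 2
  } else {
    p_wet <- rep(0.30, 365)
  }
  wet <- stats::runif(365) < p_wet
  amounts <- ifelse(wet, stats::rgamma(365, shape = 0.9, scale = 7), 0)
  target <- stats::runif(1, zone$annual_rainfall_range[1],
                         zone$annual_rainfall_range[2])
  s <- sum(amounts)
  rain <- if (s > 0) amounts * (target / s) else {
    a <- numeric(365); a[183] <- target; a
  }

  rh <- 55 + 25 * as.numeric(rain > 0) + stats::rnorm(365, sd = 7)
  rh <- pmin(100, pmax(20, rh))

  list(daily_temp = temp, daily_rain = rain, daily_rh = rh)
}
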