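#' Simulate biweekly NDVI and EVI keyed to a stage timeline
#'
#' Both indices follow a shared double-logistic latent seasonal curve:
#' a green-up rise centered between the budburst and flowering onsets and a
#' senescence decline starting about three weeks after the harvest onset
#' (no decline if harvest is never reached). NDVI and EVI are affine
#' transforms of the latent curve with independent bounded noise, clipped to
#' [0.10, 0.85] and [0.08, 0.75] respectively. Noise is uniform and bounded
#' so that clean consecutive biweekly NDVI changes never exceed 0.28 -- the
#' largest change observed in clean reference trajectories -- which keeps
#' clean data strictly below the 0.3 spike-filter threshold.
#'
#' @param timeline A \code{stage_timeline} from
#'   \code{\link{compute_gdd_and_stages}}.
#' @param seed Integer seed.
#' @param noise_half_width Half-width of the uniform observation noise
#'   (default 0.03; 0 gives the deterministic smooth curve).
#' @return List with numeric 26-vectors \code{ndvi} and \code{evi} and the
#'   noise-free \code{latent} curve.
#' @export
simulate_vegetation <- function(timeline, seed, noise_half_width = 0.03) {
  set.seed(as.integer(seed))
  on_day <- timeline$onset_season_day
  t_rise <- if (all(c("budburst", "flowering") %in% names(on_day))) {
    on_day[["budburst"]] +
      0.35 * (on_day[["flowering"]] - on_day[["budburst"]])
  } else if ("budburst" %in% names(on_day)) {
    on_day[["budburst"]] + 20
  } else 400  # never greens up
  t_fall <- if ("harvest" %in% names(on_day)) on_day[["harvest"]] + 40 else 470

  mid <- (seq_len(N_INTERVALS) - 1L) * DAYS_PER_INTERVAL + 8L
  latent <- stats::plogis((mid - t_rise) / 12) *
    (1 - stats::plogis((mid - t_fall) / 28))

  ndvi_base <- stats::runif(1, 0.15, 0.19)
  ndvi_gain <- stats::runif(1, 0.52, 0.62)
  evi_base <- stats::runif(1, 0.13, 0.16)
  evi_gain <- ndvi_gain * 0.82

  ndvi <- ndvi_base + ndvi_gain * latent +
    stats::runif(N_INTERVALS, -noise_half_width, noise_half_width)
  evi <- evi_base + evi_gain * latent +
    stats::runif(N_INTERVALS, -noise_half_width, noise_half_width)

  list(ndvi = pmin(0.85, pmax(0.10, ndvi)),
       evi = pmin(0.75, pmax(0.08, evi)),
       latent = latent)
}
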