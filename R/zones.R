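#' Agroecological zone presets
#'
#' Climate presets for the three agroecological zones represented in the
#' dataset: Mediterranean (California, southern Europe), subtropical
#' (South Australia) and temperate (central Europe). Each preset carries the
#' annual-rainfall interval the zone's sites are drawn in, the mean and
#' seasonal amplitude of daily temperature, a typical season start
#' day-of-year, the temperature noise level, and bounding boxes around the
#' viticultural regions the zone represents (used only to label sites with
#' plausible coordinates).
#'
#' Zone annual rainfall: Mediterranean 600--800 mm, subtropical 400--550 mm,
#' temperate 700--900 mm. Southern-hemisphere zones (subtropical) carry a
#' 182-day phase shift; all simulated series are indexed season-relative, so
#' the shift only affects the reported season start day-of-year.
#'
#' @param name One of \code{"mediterranean"}, \code{"subtropical"},
#'   \code{"temperate"}.
#' @return A \code{zone_preset} list.
#' @export
zone_preset <- function(name) {
  presets <- list(
    mediterranean = list(
      name = "mediterranean",
      annual_rainfall_range = c(600, 800),
      temp_mean = 13.5, temp_amplitude = 8.0,
      season_start_doy = 60L, noise_sd = 1.6,
      southern_hemisphere = FALSE,
      wet_season_winter = TRUE,
      boxes = list(
        napa    = c(lat = 38.5, lon = -122.5),
        ribera  = c(lat = 41.7, lon = -4.7),
        tuscany = c(lat = 43.5, lon = 11.2)
      )
    ),
    subtropical = list(
      name = "subtropical",
      annual_rainfall_range = c(400, 550),
      temp_mean = 14.5, temp_amplitude = 7.0,
      season_start_doy = 244L, noise_sd = 1.6,
      southern_hemisphere = TRUE,
      wet_season_winter = TRUE,
      boxes = list(
        barossa  = c(lat = -34.5, lon = 138.9),
        riverina = c(lat = -34.2, lon = 146.0)
      )
    ),
    temperate = list(
      name = "temperate",
      annual_rainfall_range = c(700, 900),
      temp_mean = 13.0, temp_amplitude = 8.0,
      season_start_doy = 75L, noise_sd = 1.8,
      southern_hemisphere = FALSE,
      wet_season_winter = FALSE,
      boxes = list(
        bordeaux = c(lat = 44.8, lon = -0.6),
        rheingau = c(lat = 50.0, lon = 8.0)
      )
    )
  )
  if (!name %in% names(presets)) {
    vp_stop("unknown zone name: '", name,
            "' (expected mediterranean, subtropical or temperate)")
  }
  structure(presets[[name]], class = "zone_preset")
}

zone_names <- function() c("mediterranean", "subtropical", "temperate")
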