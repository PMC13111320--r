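#' Read a dataset written by \code{\link{write_dataset}}
#'
#' Reconstructs the \code{site_series} list (including stage timelines) from
#' the vegetation, weather, labels and onsets CSVs.
#'
#' @param dir Directory containing the CSV files.
#' @return A \code{vp_dataset}.
#' @export
read_dataset <- function(dir) {
  veg <- utils::read.csv(file.path(dir, "vegetation.csv"))
  wx <- utils::read.csv(file.path(dir, "weather.csv"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  ons_path <- file.path(dir, "onsets.csv")
  ons <- if (file.exists(ons_path)) utils::read.csv(ons_path) else NULL

  sites <- lapply(unique(veg$site_id), function(id) {
    v <- veg[veg$site_id == id, ][order(veg$interval[veg$site_id == id]), ]
    w <- wx[wx$site_id == id, ][order(wx$season_day[wx$site_id == id]), ]
    l <- lab[lab$site_id == id, ][order(lab$interval[lab$site_id == id]), ]
    season_start <- w$doy[w$season_day == 1L]
    onset_doy <- if (!is.null(ons) && any(ons$site_id == id)) {
      o <- ons[ons$site_id == id, ]
      stats::setNames(o$onset_doy, o$stage)[
        intersect(STAGES, o$stage)]
    } else stats::setNames(numeric(0), character(0))
    tl <- structure(list(
      stage_per_interval = factor(l$stage, levels = STAGES_FULL),
      onset_season_day = onset_doy - season_start + 1L,
      onset_doy = onset_doy,
      season_start_doy = season_start,
      gdd = NULL
    ), class = "stage_timeline")
    structure(list(
      site_id = id, lat = v$lat[1], lon = v$lon[1], zone = v$zone[1],
      season_start_doy = season_start,
      daily_temp = w$temp_c, daily_rain = w$rain_mm, daily_rh = w$rh_pct,
      ndvi = v$ndvi, evi = v$evi, biweekly_rain = v$rain_mm,
      timeline = tl, contaminated_steps = integer(0), gap_steps = integer(0)
    ), class = "site_series")
  })
  if (file.exists(file.path(dir, "manifest.json"))) {
    man <- jsonlite::read_json(file.path(dir, "manifest.json"))
    attr(sites, "seed") <- man$seed
  }
  class(sites) <- "vp_dataset"
  sites
}

#' Serialize pseudo-images to a flat CSV
#'
#' One row per (site, image row): columns site_id, interval_t (the causal
#' cutoff), row, ndvi, evi, rain. Defaults to the full-season image
#' (t = 26).
#'
#' @param dataset Imputed \code{vp_dataset}.
#' @param norm_params A \code{normalization_params}.
#' @param path Output CSV path.
#' @param t Causal cutoff used for every site (default 26).
#' @return \code{path}, invisibly.
#' @export
write_pseudo_images <- function(dataset, norm_params, path,
                                t = N_INTERVALS) {
  rows <- do.call(rbind, lapply(dataset, function(s) {
    img <- build_pseudo_image(s, t, norm_params)
    data.frame(site_id = s$site_id, interval_t = t,
               row = seq_len(N_INTERVALS),
               ndvi = img[, 1], evi = img[, 2], rain = img[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write normalization parameters as JSON
#'
#' @param norm_params A \code{normalization_params}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_norm_params <- function(norm_params, path) {
  jsonlite::write_json(lapply(unclass(norm_params), as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read normalization parameters from JSON
#'
#' @param path JSON path written by \code{\link{write_norm_params}}.
#' @return A \code{normalization_params}.
#' @export
read_norm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(x, as.numeric), class = "normalization_params")
}
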