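#' Simulate one site-season
#'
#' Chains weather simulation, GDD staging, vegetation simulation and
#' biweekly rainfall aggregation into a single \code{site_series}. Biweekly
#' rainfall is clipped at 150 mm (the documented biweekly maximum).
#'
#' @param zone Zone name or \code{\link{zone_preset}}.
#' @param site_id Character site identifier.
#' @param seed Integer seed.
#' @param rule A \code{\link{gdd_rule}}.
#' @return A \code{site_series} list.
#' @export
simulate_site <- function(zone, site_id, seed, rule = gdd_rule()) {
  if (is.character(zone)) zone <- zone_preset(zone)
  # site-level thermal variability (microclimate): shifts stage onsets by a
  # few days so the classifier cannot rely on interval position alone
  set.seed(derive_seed(seed, 4L))
  zone$temp_mean <- zone$temp_mean + stats::runif(1, -0.7, 0.7)
  wx <- simulate_weather(zone, derive_seed(seed, 1L))
  tl <- compute_gdd_and_stages(wx$daily_temp, rule, zone$season_start_doy)
  veg <- simulate_vegetation(tl, derive_seed(seed, 2L))

  set.seed(derive_seed(seed, 3L))
  anchor <- zone$boxes[[randi(1L, length(zone$boxes))]]
  lat <- anchor[["lat"]] + stats::runif(1, -0.4, 0.4)
  lon <- anchor[["lon"]] + stats::runif(1, -0.4, 0.4)

  structure(list(
    site_id = site_id,
    lat = lat, lon = lon,
    zone = zone$name,
    season_start_doy = zone$season_start_doy,
    daily_temp = wx$daily_temp,
    daily_rain = wx$daily_rain,
    daily_rh = wx$daily_rh,
    ndvi = veg$ndvi,
    evi = veg$evi,
    biweekly_rain = pmin(150, aggregate_rainfall(wx$daily_rain)),
    timeline = tl,
    contaminated_steps = integer(0),
    gap_steps = integer(0)
  ), class = "site_series")
}

#' Simulate a multi-site dataset
#'
#' Generates \code{n_sites} site-seasons across the three agroecological
#' zones in the proportions of \code{zone_mix} (largest-remainder rounding,
#' so n = 3000 with mix 0.4/0.3/0.3 gives exactly 1200/900/900), then applies
#' \code{\link{corrupt_series}} to each site. Deterministic under
#' \code{seed}.
#'
#' @param n_sites Number of sites (>= 1).
#' @param zone_mix Proportions for (mediterranean, subtropical, temperate);
#'   must sum to 1.
#' @param seed Integer seed.
#' @param cloud_rate Per-interval spike probability (default 0.0015, giving
#'   about 3 percent of series at least one spike).
#' @param gap_mix Gap-length class weights (default
#'   \code{\link{default_gap_mix}}); pass \code{rep(0, 5)} to disable gaps.
#' @param gap_affected_rate Probability a series has any gap
#'   (default 0.2847).
#' @param rule A \code{\link{gdd_rule}}.
#' @return A \code{vp_dataset}: list of \code{site_series} with attributes
#'   \code{seed} and \code{params}.
#' @export
simulate_dataset <- function(n_sites, zone_mix = c(0.4, 0.3, 0.3), seed = 1L,
                             cloud_rate = 0.0015,
                             gap_mix = default_gap_mix(),
                             gap_affected_rate = 0.2847,
                             rule = gdd_rule()) {
  if (n_sites < 1) vp_stop("n_sites must be >= 1")
  if (length(zone_mix) != 3L || any(zone_mix < 0) ||
      abs(sum(zone_mix) - 1) > 1e-8) {
    vp_stop("zone_mix must be 3 non-negative proportions summing to 1")
  }
  # largest-remainder apportionment
  raw <- n_sites * zone_mix
  counts <- floor(raw)
  rem <- n_sites - sum(counts)
  if (rem > 0) {
    give <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[give] <- counts[give] + 1L
  }
  zones <- rep(zone_names(), counts)

  sites <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    s <- simulate_site(zones[i], sprintf("site_%04d", i),
                       derive_seed(seed, 10L + i), rule)
    sites[[i]] <- corrupt_series(s, cloud_rate, gap_mix,
                                 derive_seed(seed, 100000L + i),
                                 gap_affected_rate)
  }
  structure(sites, class = "vp_dataset", seed = seed,
            params = list(n_sites = n_sites, zone_mix = zone_mix,
                          cloud_rate = cloud_rate, gap_mix = gap_mix,
                          gap_affected_rate = gap_affected_rate))
}

#' @export
print.vp_dataset <- function(x, ...) {
  cat("<vp_dataset>", length(x), "site-seasons;",
      "zones:", paste(names(table(vapply(x, `[[`, "", "zone"))),
                      table(vapply(x, `[[`, "", "zone")),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Write a dataset to delimited text files
#'
#' Writes \code{vegetation.csv} (site_id, lat, lon, zone, interval, ndvi,
#' evi, rain_mm), \code{weather.csv} (site_id, season_day, doy, temp_c,
#' rain_mm, rh_pct), \code{labels.csv} (site_id, interval, stage),
#' \code{onsets.csv} (site_id, stage, onset_doy) and \code{manifest.json}
#' (seed and generator parameters).
#'
#' @param dataset A \code{vp_dataset}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  veg <- do.call(rbind, lapply(dataset, function(s) {
    data.frame(site_id = s$site_id, lat = s$lat, lon = s$lon, zone = s$zone,
               interval = seq_len(N_INTERVALS), ndvi = s$ndvi, evi = s$evi,
               rain_mm = s$biweekly_rain)
  }))
  utils::write.csv(veg, file.path(dir, "vegetation.csv"), row.names = FALSE)

  wx <- do.call(rbind, lapply(dataset, function(s) {
    data.frame(site_id = s$site_id, season_day = 1:365,
               doy = ((s$season_start_doy - 1L + 0:364) %% 365L) + 1L,
               temp_c = s$daily_temp, rain_mm = s$daily_rain,
               rh_pct = s$daily_rh)
  }))
  utils::write.csv(wx, file.path(dir, "weather.csv"), row.names = FALSE)

  lab <- do.call(rbind, lapply(dataset, function(s) {
    data.frame(site_id = s$site_id, interval = seq_len(N_INTERVALS),
               stage = as.character(s$timeline$stage_per_interval))
  }))
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)

  ons <- do.call(rbind, lapply(dataset, function(s) {
    od <- s$timeline$onset_doy
    if (!length(od)) return(NULL)
    data.frame(site_id = s$site_id, stage = names(od), onset_doy = unname(od))
  }))
  utils::write.csv(ons, file.path(dir, "onsets.csv"), row.names = FALSE)

  manifest <- c(list(seed = attr(dataset, "seed")), attr(dataset, "params"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
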