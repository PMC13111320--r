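test_that("zone presets enforce the documented annual rainfall ranges", {
  for (s in 1:6) {
    wx <- simulate_weather("mediterranean", s)
    expect_gte(sum(wx$daily_rain), 600)
    expect_lte(sum(wx$daily_rain), 800)
  }
  expect_true(all(simulate_weather("subtropical", 3)$daily_rain >= 0))
  ann_sub <- sum(simulate_weather("subtropical", 3)$daily_rain)
  expect_true(ann_sub >= 400 && ann_sub <= 550)
  ann_tmp <- sum(simulate_weather("temperate", 3)$daily_rain)
  expect_true(ann_tmp >= 700 && ann_tmp <= 900)
  expect_error(zone_preset("tundra"), "unknown zone")
})

test_that("degenerate weather settings give a constant temperature", {
  z <- zone_preset("mediterranean")
  z$noise_sd <- 0
  z$temp_amplitude <- 0
  wx <- simulate_weather(z, 1)
  expect_equal(wx$daily_temp, rep(z$temp_mean, 365))
})

test_that("weather simulation is deterministic under the seed", {
  expect_identical(simulate_weather("temperate", 7),
                   simulate_weather("temperate", 7))
  expect_false(identical(simulate_weather("temperate", 7)$daily_rain,
                         simulate_weather("temperate", 8)$daily_rain))
})

test_that("relative humidity is elevated on rain days and bounded", {
  wx <- simulate_weather("mediterranean", 4)
  expect_true(all(wx$daily_rh >= 20 & wx$daily_rh <= 100))
  wet <- wx$daily_rain > 0
  expect_gt(mean(wx$daily_rh[wet]), mean(wx$daily_rh[!wet]))
})

test_that("GDD staging matches hand-computed onsets at constant temperature", {
  tl <- compute_gdd_and_stages(rep(20, 365), gdd_rule(), season_start_doy = 1L)
  # 10 GDD/day: thresholds 50/400/1000/1400 cross on days 5/40/100/140
  expect_equal(unname(tl$onset_season_day),
               c(5L, 40L, 100L, 140L))
  expect_equal(unname(tl$onset_doy["flowering"]), 40)
})

test_that("no thermal accumulation leaves the season in pre_season", {
  tl <- compute_gdd_and_stages(rep(10, 365), gdd_rule())
  expect_true(all(tl$stage_per_interval == "pre_season"))
  expect_length(tl$onset_doy, 0)
})

test_that("staging agrees with a brute-force day-by-day oracle", {
  rule <- gdd_rule()
  set.seed(301)
  for (rep_i in 1:50) {
    temp <- runif(1, 10, 16) - runif(1, 5, 9) * cos(2 * pi * (0:364) / 365) +
      rnorm(365, sd = 2)
    tl <- compute_gdd_and_stages(temp, rule)
    # oracle: explicit loop accumulation
    acc <- 0
    onset <- rep(NA_integer_, 4)
    for (d in 1:365) {
      acc <- acc + max(0, temp[d] - rule$base_temp)
      for (k in 1:4) {
        if (is.na(onset[k]) && acc >= rule$onsets[k]) onset[k] <- d
      }
    }
    names(onset) <- names(rule$onsets)
    expect_equal(tl$onset_season_day, onset[!is.na(onset)])
    # monotone stage sequence
    expect_true(all(diff(as.integer(tl$stage_per_interval)) >= 0))
    # first interval carrying a stage is the first whose midpoint >= onset
    for (st in names(tl$onset_season_day)) {
      first <- which(tl$stage_per_interval == st)[1]
      if (!is.na(first)) {
        mids <- (seq_len(26) - 1) * 14 + 8
        expect_identical(first,
                         which(mids >= tl$onset_season_day[[st]])[1])
      }
    }
  }
})

test_that("onset order is strictly increasing whenever all stages occur", {
  ds <- clean_dataset()
  for (s in ds) {
    od <- s$timeline$onset_season_day
    if (length(od) == 4) expect_true(all(diff(od) > 0))
  }
})

test_that("noise-free vegetation is a smooth rise/plateau/decline curve", {
  tl <- compute_gdd_and_stages(
    14 - 8 * cos(2 * pi * (0:364) / 365), gdd_rule())
  veg <- simulate_vegetation(tl, seed = 2, noise_half_width = 0)
  expect_identical(simulate_vegetation(tl, 2, 0)$ndvi, veg$ndvi)
  d <- diff(veg$ndvi)
  turn <- which.max(veg$ndvi)
  expect_true(all(d[seq_len(turn - 1)] >= 0))   # monotone rise to the peak
  expect_true(all(d[turn:length(d)] <= 0))      # monotone decline after
  expect_true(all(veg$ndvi >= 0.10 & veg$ndvi <= 0.85))
  expect_true(all(veg$evi >= 0.08 & veg$evi <= 0.75))
})

test_that("clean trajectories never exceed the 0.28 biweekly NDVI change", {
  ds <- clean_dataset()
  dmax <- max(vapply(ds, function(s) max(abs(diff(s$ndvi))), numeric(1)))
  expect_lte(dmax, 0.28)
})

test_that("corruption is a no-op at zero rates", {
  s <- simulate_site("mediterranean", "s1", 5)
  s2 <- corrupt_series(s, cloud_rate = 0, gap_mix = rep(0, 5), seed = 9)
  expect_identical(s2$ndvi, s$ndvi)
  expect_identical(s2$evi, s$evi)
  expect_length(s2$contaminated_steps, 0)
  expect_error(corrupt_series(s, 0.1, c(0.5, 0.2, 0.1, 0.1, 0.2), 1),
               "sum to 1")
})

test_that("injected spike depths center on 0.47 and gap classes follow the mix", {
  depths <- c(); lens <- c()
  mix <- default_gap_mix()
  for (i in 1:400) {
    s <- simulate_site("mediterranean", paste0("s", i), 1000 + i)
    s2 <- corrupt_series(s, cloud_rate = 0.15, gap_mix = mix, seed = 2000 + i,
                         gap_affected_rate = 1)
    depths <- c(depths, unname(s2$spike_depth))
    if (length(s2$gap_steps)) {
      r <- rle(seq_len(26) %in% s2$gap_steps)
      lens <- c(lens, r$lengths[r$values])
    }
  }
  expect_equal(mean(depths), 0.47, tolerance = 0.02)
  cls <- cut(lens, c(0, 1, 2, 3, 6, Inf), labels = names(mix))
  obs <- as.numeric(table(cls)) / length(lens)
  # class frequencies within a generous binomial band around the mix
  se <- sqrt(mix * (1 - mix) / length(lens))
  expect_true(all(abs(obs - mix) < 4 * se + 0.02))
})

test_that("zone apportionment reproduces the documented 1200/900/900 split", {
  # largest-remainder arithmetic, checked without simulating 3000 sites
  raw <- 3000 * c(0.4, 0.3, 0.3)
  expect_identical(floor(raw), c(1200, 900, 900))
  ds <- simulate_dataset(10, zone_mix = c(0.4, 0.3, 0.3), seed = 1,
                         cloud_rate = 0, gap_mix = rep(0, 5),
                         gap_affected_rate = 0)
  expect_equal(as.vector(table(vapply(ds, `[[`, "", "zone"))[
    c("mediterranean", "subtropical", "temperate")]), c(4L, 3L, 3L))
  expect_error(simulate_dataset(10, zone_mix = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("single-site datasets satisfy the series invariants", {
  ds <- simulate_dataset(1, seed = 3)
  s <- ds[[1]]
  expect_length(s$ndvi, 26)
  obs <- s$ndvi[!is.na(s$ndvi)]
  expect_true(all(obs >= -0.2 & obs <= 1))
  expect_true(all(s$biweekly_rain >= 0 & s$biweekly_rain <= 150))
  expect_s3_class(s$timeline, "stage_timeline")
})

test_that("dataset generation is byte-identical under the same seed", {
  d1 <- simulate_dataset(5, seed = 77)
  d2 <- simulate_dataset(5, seed = 77)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})

test_that("dataset CSV round-trip preserves vegetation values", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(3, seed = 5)
  write_dataset(ds, dir)
  veg <- read.csv(file.path(dir, "vegetation.csv"))
  expect_equal(nrow(veg), 3 * 26)
  expect_equal(veg$ndvi[veg$site_id == ds[[2]]$site_id], ds[[2]]$ndvi)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 5)
})

test_that("distributional targets hold over a large clean sample", {
  ds <- simulate_dataset(1000, seed = 202, cloud_rate = 0,
                         gap_mix = rep(0, 5), gap_affected_rate = 0)
  nd <- unlist(lapply(ds, `[[`, "ndvi"))
  ev <- unlist(lapply(ds, `[[`, "evi"))
  rain <- unlist(lapply(ds, `[[`, "biweekly_rain"))
  expect_true(min(nd) >= 0.10 && max(nd) <= 0.85)
  expect_true(min(ev) >= 0.08 && max(ev) <= 0.75)
  expect_true(min(rain) >= 0 && max(rain) <= 150)
  expect_equal(mean(nd), 0.45, tolerance = 0.05)
  expect_equal(mean(ev), 0.38, tolerance = 0.05)
})
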