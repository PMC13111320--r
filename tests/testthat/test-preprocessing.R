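test_that("spike filter flags dips and respects the strict 0.3 boundary", {
  flat <- rep(0.4, 26)
  expect_false(any(flag_spikes(flat)))

  x <- rep(0.65, 26)
  x[10] <- 0.20  # dip of 0.45 then recovery
  fl <- flag_spikes(x)
  expect_true(fl[10])
  expect_equal(sum(fl), 1L)

  y <- rep(0.5, 26)
  y[12] <- 0.2  # delta exactly 0.3: strictly above required
  expect_false(any(flag_spikes(y)))

  expect_error(flag_spikes(rep(NA_real_, 26)), "observed")
})

test_that("spike deltas skip missing steps", {
  x <- rep(0.5, 26)
  x[5] <- NA
  x[6] <- 0.1  # previous observed is x[4] = 0.5, drop 0.4
  expect_true(flag_spikes(x)[6])
})

test_that("series drop rule uses the strict 30 percent fraction", {
  mk <- function(n_bad) {
    s <- simulate_site("temperate", "x", 3)
    s$ndvi[seq_len(n_bad)] <- NA
    s$evi[seq_len(n_bad)] <- NA
    ds <- list(s)
    class(ds) <- "vp_dataset"
    ds
  }
  expect_equal(qc_partition(mk(9))$dropped, "x")   # 9/26 = 34.6% > 30%
  expect_length(qc_partition(mk(7))$dropped, 0)    # 7/26 = 26.9% < 30%
  clean <- qc_partition(mk(0))
  expect_length(clean$dropped, 0)
  expect_identical(clean$kept[[1]]$ndvi, mk(0)[[1]]$ndvi)
})

test_that("gap segmentation finds maximal runs with correct anchors", {
  m <- rep(FALSE, 26)
  m[c(5, 6, 12)] <- TRUE
  g <- find_gaps(m)
  expect_length(g, 2)
  expect_equal(g[[1]]$start, 5L); expect_equal(g[[1]]$length, 2L)
  expect_equal(g[[1]]$left_anchor, 4L); expect_equal(g[[1]]$right_anchor, 7L)
  expect_equal(g[[2]]$start, 12L); expect_equal(g[[2]]$length, 1L)

  expect_length(find_gaps(rep(FALSE, 26)), 0)

  e <- rep(FALSE, 26); e[1] <- TRUE; e[26] <- TRUE
  ge <- find_gaps(e)
  expect_true(is.na(ge[[1]]$left_anchor))
  expect_true(is.na(ge[[2]]$right_anchor))
})

test_that("imputation dispatch is exhaustive and exclusive over gap lengths", {
  expect_equal(vapply(1:8, vitiphen:::imputation_method_for, ""),
               c("linear", "spline", "spline", rep("loess", 5)))
})

test_that("linear branch is exact on linear signals", {
  x <- 0.02 * (1:26)
  xm <- x; xm[9] <- NA
  expect_equal(impute_gaps(xm), x, tolerance = 1e-12)
})

test_that("spline branch recovers cubic signals on interior gaps", {
  t <- 1:26
  x <- 0.3 + 0.01 * t - 4e-4 * t^2 + 1.2e-5 * t^3
  xm <- x; xm[12:13] <- NA
  expect_equal(impute_gaps(xm), x, tolerance = 1e-6)
  xm3 <- x; xm3[8:10] <- NA
  expect_equal(impute_gaps(xm3), x, tolerance = 1e-6)
})

test_that("imputation never alters observed values and is idempotent", {
  set.seed(4)
  x <- 0.4 + 0.2 * sin(2 * pi * (1:26) / 26) + rnorm(26, 0, 0.01)
  expect_identical(impute_gaps(x), x)
  xm <- x; xm[c(3, 15:19)] <- NA
  filled <- impute_gaps(xm)
  expect_identical(filled[!is.na(xm)], x[!is.na(xm)])
  expect_false(anyNA(filled))
})

test_that("long gaps recover a smooth seasonal signal within 1.5x noise", {
  set.seed(88)
  rmse_all <- replicate(12, {
    sd_noise <- 0.03
    x <- 0.45 + 0.12 * sin(2 * pi * (1:26) / 26) + rnorm(26, 0, sd_noise)
    start <- sample(5:17, 1)
    xm <- x; xm[start:(start + 4)] <- NA   # L = 5 -> LOESS branch
    filled <- impute_gaps(xm)
    truth <- 0.45 + 0.12 * sin(2 * pi * (start:(start + 4)) / 26)
    sqrt(mean((filled[start:(start + 4)] - truth)^2))
  })
  expect_lte(mean(rmse_all), 1.5 * 0.03)
})

test_that("edge gaps use nearest-value extension for short runs", {
  x <- seq(0.3, 0.8, length.out = 26)
  xm <- x; xm[1:2] <- NA
  filled <- impute_gaps(xm)
  expect_equal(filled[1:2], rep(x[3], 2))
})

test_that("rainfall aggregation preserves totals over the 364-day window", {
  expect_equal(aggregate_rainfall(rep(1, 365)), rep(14, 26))
  one <- rep(0, 365); one[40] <- 30
  agg <- aggregate_rainfall(one)
  expect_equal(sum(agg > 0), 1)
  expect_equal(max(agg), 30)
  set.seed(2)
  r <- rgamma(365, 0.5, 1)
  expect_equal(sum(aggregate_rainfall(r)), sum(r[1:364]))
  expect_error(aggregate_rainfall(rep(1, 100)), "too short")
})

test_that("min-max normalization matches the documented arithmetic", {
  expect_equal(normalize_minmax(0.10, c(0.10, 0.85)), 0)
  expect_equal(normalize_minmax(0.85, c(0.10, 0.85)), 1)
  expect_equal(normalize_minmax(0.45, c(0.10, 0.85)), 0.35 / 0.75,
               tolerance = 1e-12)
  x <- runif(50)
  rng <- c(-2, 3)
  expect_equal(normalize_minmax(normalize_minmax(x, rng), rng, invert = TRUE),
               x, tolerance = 1e-12)
  expect_error(normalize_minmax(1, c(2, 2)), "degenerate")
  # out-of-range test-time inputs are clipped
  expect_equal(normalize_minmax(c(-5, 5), c(0, 1)), c(0, 1))
})

test_that("normalization fitted on training data maps it into [0, 1]", {
  pp <- preprocess_dataset(clean_dataset())
  np <- pp$norm_params
  for (s in pp$dataset[1:10]) {
    expect_true(all(normalize_minmax(s$ndvi, np$ndvi) >= 0))
    expect_true(all(normalize_minmax(s$ndvi, np$ndvi) <= 1))
    expect_true(all(normalize_minmax(s$biweekly_rain, np$rain) <= 1))
  }
})

test_that("pseudo-images are causal 26 x 3 matrices in canonical order", {
  pp <- preprocess_dataset(clean_dataset())
  s <- pp$dataset[[1]]
  np <- pp$norm_params
  full <- build_pseudo_image(s, 26L, np)
  expect_equal(dim(full), c(26L, 3L))
  expect_true(all(full >= 0 & full <= 1))
  expect_false(any(apply(full[, 1:2], 1, function(r) all(r == 0))))

  one <- build_pseudo_image(s, 1L, np)
  expect_true(all(one[2:26, ] == 0))
  expect_equal(attr(one, "valid_rows"), 1L)

  # feature order is part of the contract
  expect_equal(unname(full[5, 1]), normalize_minmax(s$ndvi[5], np$ndvi))
  expect_equal(unname(full[5, 3]),
               normalize_minmax(s$biweekly_rain[5], np$rain))
  expect_false(isTRUE(all.equal(full[, 1], full[, 3])))
  expect_error(build_pseudo_image(s, 27L, np), "1..26")
})

test_that("gap census reproduces the documented percentages", {
  counts <- c("1" = 3842, "2" = 894, "3" = 306, "4-6" = 142, ">6" = 53)
  missing <- c(3842, 1788, 918, 710, 955)
  cen <- gap_census(counts, missing, total_series = 10000,
                    timesteps_per_series = 26, affected_series = 2847)
  expect_equal(cen$share_pct, c(46.8, 21.8, 11.2, 8.6, 11.6))
  expect_equal(attr(cen, "overall_missing_pct"), 3.16)
  expect_equal(attr(cen, "affected_pct"), 28.47)

  solo <- gap_census(c("1" = 10), 10, total_series = 5)
  expect_equal(solo$share_pct, 100)
  expect_error(gap_census(c("1" = 0), 0, 10), "zero totals")
})

test_that("the spike filter is transparent on clean data and catches spikes", {
  ds <- clean_dataset()
  flags <- vapply(ds, function(s) sum(flag_spikes(s$ndvi)), numeric(1))
  expect_equal(sum(flags), 0)

  # corrupted data: >= 90 percent of injected spikes flagged
  hit <- 0L; tot <- 0L
  for (i in seq_len(150)) {
    s <- simulate_site(c("mediterranean", "subtropical",
                         "temperate")[1 + i %% 3], paste0("c", i), 400 + i)
    s2 <- corrupt_series(s, cloud_rate = 0.12, gap_mix = rep(0, 5),
                         seed = 900 + i)
    if (!length(s2$contaminated_steps)) next
    fl <- flag_spikes(s2$ndvi)
    hit <- hit + sum(fl[s2$contaminated_steps])
    tot <- tot + length(s2$contaminated_steps)
  }
  expect_gt(tot, 200)
  expect_gte(hit / tot, 0.90)
})

test_that("dataset and parameter serialization round-trips", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(3, seed = 8, cloud_rate = 0, gap_mix = rep(0, 5),
                         gap_affected_rate = 0)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back, 3)
  expect_equal(back[[1]]$ndvi, ds[[1]]$ndvi)
  expect_equal(back[[2]]$daily_temp, ds[[2]]$daily_temp)
  expect_equal(as.character(back[[3]]$timeline$stage_per_interval),
               as.character(ds[[3]]$timeline$stage_per_interval))
  expect_equal(back[[1]]$timeline$onset_doy[["flowering"]],
               ds[[1]]$timeline$onset_doy[["flowering"]])

  pp <- preprocess_dataset(ds)
  np_path <- file.path(dir, "norm.json")
  write_norm_params(pp$norm_params, np_path)
  np2 <- read_norm_params(np_path)
  expect_equal(np2$ndvi, pp$norm_params$ndvi)

  img_path <- file.path(dir, "images.csv")
  write_pseudo_images(pp$dataset, pp$norm_params, img_path)
  img <- read.csv(img_path)
  expect_equal(nrow(img), 3 * 26)
  expect_true(all(img$ndvi >= 0 & img$ndvi <= 1))
})
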