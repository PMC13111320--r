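#' Aggregate daily rainfall to biweekly sums
#'
#' Interval \code{i} is the sum of season days \code{14*(i-1)+1 .. 14*i};
#' 26 intervals cover 364 days and the total over those days is preserved.
#'
#' @param daily_rain Numeric vector of at least 364 daily values.
#' @param season_start_day First day (1-based index into \code{daily_rain})
#'   of interval 1.
#' @return Numeric 26-vector of biweekly sums (mm).
#' @export
aggregate_rainfall <- function(daily_rain, season_start_day = 1L) {
  need <- season_start_day + N_INTERVALS * DAYS_PER_INTERVAL - 1L
  if (length(daily_rain) < need) {
    vp_stop("daily rainfall vector too short for the 26-interval window")
  }
  window <- daily_rain[season_start_day:need]
  as.numeric(rowsum(window, rep(seq_len(N_INTERVALS),
                                each = DAYS_PER_INTERVAL)))
}

#' Fit min-max normalization parameters
#'
#' Per-feature minimum and maximum over the supplied series (typically the
#' training portion; fitting on the full dataset is available through the
#' caller by passing all series, but leaks test information and is off by
#' default in the pipeline).
#'
#' @param dataset A \code{vp_dataset} (series should be imputed).
#' @return A \code{normalization_params} list with per-feature
#'   \code{c(min, max)} for ndvi, evi, rain.
#' @export
fit_normalization <- function(dataset) {
  rng <- function(v) range(v, na.rm = TRUE)
  ndvi <- rng(unlist(lapply(dataset, `[[`, "ndvi")))
  evi <- rng(unlist(lapply(dataset, `[[`, "evi")))
  rain <- rng(unlist(lapply(dataset, `[[`, "biweekly_rain")))
  for (r in list(ndvi, evi, rain)) {
    if (r[2] <= r[1]) vp_stop("degenerate feature: max must exceed min")
  }
  structure(list(ndvi = ndvi, evi = evi, rain = rain),
            class = "normalization_params")
}

#' Apply (or invert) min-max normalization
#'
#' \code{x' = (x - xmin) / (xmax - xmin)}. Out-of-range inputs are clipped to
#' [0, 1] when normalizing; inversion is exact for in-range values.
#'
#' @param x Numeric vector.
#' @param range Length-2 \code{c(min, max)} from
#'   \code{\link{fit_normalization}}.
#' @param invert If TRUE, map from [0, 1] back to feature units.
#' @return Numeric vector.
#' @export
normalize_minmax <- function(x, range, invert = FALSE) {
  if (range[2] <= range[1]) vp_stop("degenerate feature: max must exceed min")
  if (invert) return(range[1] + x * (range[2] - range[1]))
  pmin(1, pmax(0, (x - range[1]) / (range[2] - range[1])))
}

#' Build the causal pseudo-image for a series at interval t
#'
#' A 26 x 3 single-channel matrix: row i holds the normalized (NDVI, EVI,
#' rainfall) of interval i for i <= t; rows beyond t are zero (causal mask).
#'
#' @param series An imputed \code{site_series}.
#' @param t Valid-rows cutoff, 1..26 (26 = full season).
#' @param params A \code{normalization_params}.
#' @return A \code{pseudo_image}: 26 x 3 matrix with attributes
#'   \code{valid_rows} and \code{feature_order}.
#' @export
build_pseudo_image <- function(series, t, params) {
  if (t < 1L || t > N_INTERVALS) vp_stop("t must be in 1..26")
  if (anyNA(series$ndvi) || anyNA(series$evi)) {
    vp_stop("series must be imputed before pseudo-image construction")
  }
  m <- matrix(0, N_INTERVALS, 3,
              dimnames = list(NULL, c("ndvi", "evi", "rain")))
  keep <- seq_len(t)
  m[keep, 1] <- normalize_minmax(series$ndvi[keep], params$ndvi)
  m[keep, 2] <- normalize_minmax(series$evi[keep], params$evi)
  m[keep, 3] <- normalize_minmax(series$biweekly_rain[keep], params$rain)
  structure(m, valid_rows = t, feature_order = c("ndvi", "evi", "rain"),
            class = "pseudo_image")
}

#' Gap census summary
#'
#' Reproduces the dataset-level missing-data accounting: per length class the
#' share of missing timesteps, the overall missing percentage, and the
#' percentage of series affected.
#'
#' @param class_gap_counts Named numeric vector of gap counts per length
#'   class, e.g. \code{c("1" = 3842, "2" = 894, ...)}.
#' @param class_missing_timesteps Missing timesteps per class (same order).
#' @param total_series Number of series in the dataset.
#' @param timesteps_per_series Timesteps per series (26).
#' @param affected_series Number of series with at least one gap (optional).
#' @return Data frame with one row per class (\code{share_pct}) plus
#'   attributes \code{overall_missing_pct} and \code{affected_pct}.
#' @export
gap_census <- function(class_gap_counts, class_missing_timesteps,
                       total_series, timesteps_per_series = N_INTERVALS,
                       affected_series = NA) {
  if (any(class_gap_counts < 0) || any(class_missing_timesteps < 0)) {
    vp_stop("counts must be non-negative")
  }
  total_missing <- sum(class_missing_timesteps)
  if (total_missing == 0 || total_series == 0) {
    vp_stop("zero totals: shares undefined")
  }
  out <- data.frame(
    class = names(class_gap_counts),
    n_gaps = as.numeric(class_gap_counts),
    missing_timesteps = as.numeric(class_missing_timesteps),
    share_pct = round(100 * class_missing_timesteps / total_missing, 1)
  )
  attr(out, "overall_missing_pct") <-
    round(100 * total_missing / (total_series * timesteps_per_series), 2)
  attr(out, "affected_pct") <- if (is.na(affected_series)) NA_real_ else
    round(100 * affected_series / total_series, 2)
  out
}

#' Run the full preprocessing pipeline on a dataset
#'
#' Spike QC, series dropping, censoring, gap imputation of NDVI and EVI,
#' and normalization-parameter fitting. Returns imputed series and the
#' fitted parameters.
#'
#' @param dataset A \code{vp_dataset}.
#' @param qc A \code{\link{qc_config}}.
#' @param imp An \code{\link{imputation_config}}.
#' @param norm_params Optional pre-fitted \code{normalization_params}
#'   (e.g. from training folds); fitted on \code{dataset} when NULL.
#' @return List: \code{dataset} (kept, imputed series), \code{dropped}
#'   (site ids), \code{norm_params}.
#' @export
preprocess_dataset <- function(dataset, qc = qc_config(),
                               imp = imputation_config(),
                               norm_params = NULL) {
  part <- qc_partition(dataset, qc)
  kept <- part$kept
  for (i in seq_along(kept)) {
    s <- kept[[i]]
    if (anyNA(s$ndvi)) s$ndvi <- impute_gaps(s$ndvi, cfg = imp)
    if (anyNA(s$evi)) s$evi <- impute_gaps(s$evi, cfg = imp)
    # keep indices within physically meaningful bounds after imputation
    s$ndvi <- pmin(1, pmax(-0.2, s$ndvi))
    s$evi <- pmin(1, pmax(-0.2, s$evi))
    kept[[i]] <- s
  }
  if (is.null(norm_params)) norm_params <- fit_normalization(kept)
  list(dataset = kept, dropped = part$dropped, norm_params = norm_params)
}
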