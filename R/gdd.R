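#' Growing-degree-day staging rule
#'
#' Stage onsets are placed where accumulated growing degree days (GDD, base
#' 10 deg C) first cross published grapevine thresholds: budburst at 50,
#' flowering at 400, veraison at 1000 and harvest at 1400 GDD. The upper
#' edges of the published bands (100, 600, 1200, 1800) are retained as
#' metadata only; for per-interval labels the stages are made contiguous --
#' a stage persists from its onset until the next stage's onset.
#'
#' @param base_temp Base temperature in deg C (default 10).
#' @param onsets Named numeric vector of onset thresholds in GDD, strictly
#'   increasing in stage order.
#' @param band_uppers Named numeric vector of band upper edges (metadata).
#' @return A \code{gdd_rule} list.
#' @export
gdd_rule <- function(base_temp = 10,
                     onsets = c(budburst = 50, flowering = 400,
                                veraison = 1000, harvest = 1400),
                     band_uppers = c(budburst = 100, flowering = 600,
                                     veraison = 1200, harvest = 1800)) {
  stopifnot(identical(names(onsets), STAGES))
  if (any(diff(onsets) <= 0)) {
    vp_stop("stage onset thresholds must be strictly increasing")
  }
  structure(list(base_temp = base_temp, onsets = onsets,
                 band_uppers = band_uppers),
            class = "gdd_rule")
}

#' Accumulate GDD and derive the stage timeline
#'
#' Cumulative GDD on season day \code{d} is
#' \code{sum(pmax(0, temp - base_temp))} from the season start through
#' \code{d}. A stage's onset is the first day on which cumulative GDD reaches
#' its threshold; the stage active on a day is the highest stage whose onset
#' threshold has been reached. Each biweekly interval is labeled with the
#' stage active at its midpoint (the 8th day of the interval). Stages whose
#' thresholds are never crossed are absent from \code{onset_doy}.
#'
#' @param daily_temp Numeric 365-vector of season-relative daily mean
#'   temperatures (deg C), day 1 = season start.
#' @param rule A \code{\link{gdd_rule}}.
#' @param season_start_doy Day of year of season day 1 (used to report
#'   onsets as day-of-year).
#' @return A \code{stage_timeline} list with \code{stage_per_interval}
#'   (factor, 26 values over pre_season..harvest), \code{onset_doy} (named
#'   vector, possibly incomplete), \code{onset_season_day},
#'   \code{season_start_doy} and the cumulative \code{gdd} vector.
#' @export
compute_gdd_and_stages <- function(daily_temp, rule = gdd_rule(),
                                   season_start_doy = 1L) {
  if (length(daily_temp) != 365L) vp_stop("daily_temp must have 365 values")
  gdd <- cumsum(pmax(0, daily_temp - rule$base_temp))

  onset_day <- vapply(rule$onsets, function(th) {
    i <- which(gdd >= th)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))

  mid_days <- (seq_len(N_INTERVALS) - 1L) * DAYS_PER_INTERVAL + 8L
  stage_idx <- vapply(mid_days, function(d) {
    sum(gdd[d] >= rule$onsets)  # 0 = pre_season
  }, numeric(1))
  stage <- factor(STAGES_FULL[stage_idx + 1L], levels = STAGES_FULL)

  present <- !is.na(onset_day)
  structure(list(
    stage_per_interval = stage,
    onset_season_day = onset_day[present],
    onset_doy = onset_day[present] + season_start_doy - 1L,
    season_start_doy = season_start_doy,
    gdd = gdd
  ), class = "stage_timeline")
}
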