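# Internal helpers shared across modules.

STAGES <- c("budburst", "flowering", "veraison", "harvest")
STAGES_FULL <- c("pre_season", STAGES)

N_INTERVALS <- 26L
DAYS_PER_INTERVAL <- 14L

`%||%` <- function(a, b) if (is.null(a)) b else a

vp_stop <- function(...) stop(..., call. = FALSE)

#' Day of year at the midpoint of a biweekly interval
#'
#' Intervals are season-relative: interval `i` covers season days
#' `14*(i-1)+1 .. 14*i`. The midpoint convention is the 8th day of the
#' interval, reported relative to the season start day-of-year.
#'
#' @param interval Integer interval index in 1..26.
#' @param season_start_doy Day of year on which the season starts.
#' @return Integer day of year.
#' @export
interval_midpoint_doy <- function(interval, season_start_doy = 1L) {
  stopifnot(all(interval >= 1L), all(interval <= N_INTERVALS))
  season_start_doy + (interval - 1L) * DAYS_PER_INTERVAL + 7L
}

# interval containing a season-relative day (1-based)
day_to_interval <- function(season_day) {
  pmin(N_INTERVALS, (as.integer(season_day) - 1L) %/% DAYS_PER_INTERVAL + 1L)
}

# draw from an integer range, inclusive on both ends (randi semantics);
# lo > hi is resolved by lo <- hi
randi <- function(lo, hi) {
  if (lo > hi) lo <- hi
  if (lo == hi) return(as.integer(lo))
  as.integer(sample(seq.int(lo, hi), 1L))
}

# seed derived from a base seed and a stream index, kept within 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}
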