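#' Risk-rule configuration
#'
#' Rain stress: biweekly rainfall above the collection-wide 75th percentile
#' coinciding with predicted flowering (fruit set is folded into the
#' flowering window). Pest risk: daily mean temperature above 22 deg C and
#' relative humidity above 70 percent within the 30 days before the
#' predicted veraison onset (grapevine moth conditions).
#'
#' @param rain_percentile Percentile of the collection's biweekly rainfall
#'   (default 75).
#' @param pest_temp_c Temperature threshold, deg C (default 22).
#' @param pest_rh_pct Relative-humidity threshold, percent (default 70).
#' @param pre_veraison_window_days Length of the pre-veraison window
#'   (default 30).
#' @return A \code{risk_rule_config} list.
#' @export
risk_rule_config <- function(rain_percentile = 75, pest_temp_c = 22,
                             pest_rh_pct = 70,
                             pre_veraison_window_days = 30L) {
  if (rain_percentile <= 0 || rain_percentile >= 100) {
    vp_stop("rain_percentile must be in (0, 100)")
  }
  if (pre_veraison_window_days <= 0) vp_stop("window must be positive")
  structure(list(rain_percentile = rain_percentile,
                 pest_temp_c = pest_temp_c, pest_rh_pct = pest_rh_pct,
                 pre_veraison_window_days = as.integer(pre_veraison_window_days)),
            class = "risk_rule_config")
}

#' Rain-stress alerts for one site
#'
#' An alert is issued for each interval whose biweekly rainfall strictly
#' exceeds the threshold and whose predicted stage is flowering; the alert
#' date is the interval midpoint.
#'
#' @param pred_stages Character 26-vector of predicted stages.
#' @param biweekly_rain Numeric 26-vector (mm).
#' @param rain_threshold Rainfall threshold in mm (the caller computes the
#'   percentile over the evaluation collection; see
#'   \code{\link{rain_threshold_from}}).
#' @param season_start_doy Day of year of season day 1.
#' @param site_id Site identifier.
#' @return Data frame of alerts (site_id, alert_type, doy, stage_context,
#'   trigger_rain_mm), zero rows if none.
#' @export
detect_rain_risk <- function(pred_stages, biweekly_rain, rain_threshold,
                             season_start_doy = 1L, site_id = "site") {
  if (!length(biweekly_rain) || all(is.na(biweekly_rain))) {
    vp_stop("empty rainfall series")
  }
  hit <- which(pred_stages == "flowering" & biweekly_rain > rain_threshold)
  data.frame(site_id = rep(site_id, length(hit)),
             alert_type = rep("rain", length(hit)),
             doy = if (length(hit)) interval_midpoint_doy(hit, season_start_doy)
                   else integer(0),
             stage_context = rep("flowering", length(hit)),
             trigger_rain_mm = biweekly_rain[hit],
             stringsAsFactors = FALSE)
}

#' Collection-wide rainfall percentile threshold
#'
#' @param dataset A \code{vp_dataset}.
#' @param percentile Percentile in (0, 100).
#' @return Scalar threshold in mm.
#' @export
rain_threshold_from <- function(dataset, percentile = 75) {
  as.numeric(stats::quantile(unlist(lapply(dataset, `[[`, "biweekly_rain")),
                             percentile / 100, na.rm = TRUE, names = FALSE))
}

#' Pest-risk alerts for one site
#'
#' Scans the 30 days before the predicted veraison onset for days with
#' temperature above 22 deg C and relative humidity above 70 percent;
#' consecutive qualifying days collapse into one alert dated at the run's
#' first day.
#'
#' @param veraison_onset_doy Predicted veraison onset (day of year).
#' @param daily_temp,daily_rh Season-relative 365-vectors.
#' @param cfg A \code{\link{risk_rule_config}}.
#' @param season_start_doy Day of year of season day 1.
#' @param site_id Site identifier.
#' @return Data frame of alerts (site_id, alert_type, doy, stage_context,
#'   trigger_temp_c, trigger_rh_pct).
#' @export
detect_pest_risk <- function(veraison_onset_doy, daily_temp, daily_rh,
                             cfg = risk_rule_config(), season_start_doy = 1L,
                             site_id = "site") {
  if (is.na(veraison_onset_doy)) {
    return(data.frame(site_id = character(0), alert_type = character(0),
                      doy = integer(0), stage_context = character(0),
                      trigger_temp_c = numeric(0),
                      trigger_rh_pct = numeric(0)))
  }
  onset_day <- veraison_onset_doy - season_start_doy + 1L  # season-relative
  window <- seq.int(onset_day - cfg$pre_veraison_window_days, onset_day - 1L)
  window <- window[window >= 1L & window <= 365L]
  if (anyNA(daily_temp[window]) || anyNA(daily_rh[window])) {
    vp_stop("missing weather covariates on season days ",
            paste(window[is.na(daily_temp[window]) | is.na(daily_rh[window])],
                  collapse = ", "))
  }
  qual <- daily_temp[window] > cfg$pest_temp_c &
    daily_rh[window] > cfg$pest_rh_pct
  if (!any(qual)) {
    return(data.frame(site_id = character(0), alert_type = character(0),
                      doy = integer(0), stage_context = character(0),
                      trigger_temp_c = numeric(0),
                      trigger_rh_pct = numeric(0)))
  }
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  first_days <- window[starts[r$values]]
  data.frame(site_id = rep(site_id, length(first_days)),
             alert_type = rep("pest", length(first_days)),
             doy = first_days + season_start_doy - 1L,
             stage_context = rep("pre_veraison", length(first_days)),
             trigger_temp_c = daily_temp[first_days],
             trigger_rh_pct = daily_rh[first_days],
             stringsAsFactors = FALSE)
}

#' Stage-specific resilience recommendation
#'
#' Static risk grades and actions per stage: budburst (Low/Low), flowering
#' (High rain / Medium pest), veraison (Low/High), harvest (Medium/Low).
#'
#' @param stage One of the four stage names.
#' @return List: \code{rain_risk}, \code{pest_risk}, \code{action}.
#' @export
recommend <- function(stage) {
  tbl <- list(
    budburst = list(rain_risk = "Low", pest_risk = "Low",
                    action = "Monitor soil moisture, prepare irrigation"),
    flowering = list(rain_risk = "High", pest_risk = "Medium",
                     action = "Deploy rain covers, monitor humidity"),
    veraison = list(rain_risk = "Low", pest_risk = "High",
                    action = "Apply biopesticides, increase scouting"),
    harvest = list(rain_risk = "Medium", pest_risk = "Low",
                   action = "Delay harvest if rain expected, prepare storage")
  )
  if (!stage %in% names(tbl)) vp_stop("unknown stage: ", stage)
  tbl[[stage]]
}

#' Event-matching configuration
#'
#' @param tp_tolerance_days Same-site same-type alert within this window
#'   makes an event a true positive (default 5).
#' @param fp_exclusion_days An alert with no same-site same-type event
#'   within this window is a false positive (default 10; alerts landing in
#'   the 5-10 day band count neither way, excluding possible lapses in
#'   reporting).
#' @return A \code{match_config} list.
#' @export
match_config <- function(tp_tolerance_days = 5L, fp_exclusion_days = 10L) {
  if (fp_exclusion_days < tp_tolerance_days) {
    vp_stop("fp_exclusion_days must be >= tp_tolerance_days")
  }
  structure(list(tp_tolerance_days = as.integer(tp_tolerance_days),
                 fp_exclusion_days = as.integer(fp_exclusion_days)),
            class = "match_config")
}

#' Match alerts against documented events
#'
#' Greedy one-to-one matching by smallest day gap (ties broken by earlier
#' event date): an event is a true positive when a same-site same-type alert
#' lies within the tolerance window and each alert consumes at most one
#' event. Unmatched events are false negatives. An alert is a false positive
#' only when no same-site same-type event exists within the (wider)
#' exclusion window. TP + FN always equals the event count.
#'
#' @param alerts Data frame with columns site_id, alert_type, doy.
#' @param events Data frame with columns site_id, event_type, doy.
#' @param cfg A \code{\link{match_config}}.
#' @return Data frame with one row per type present in either input:
#'   type, TP, FN, FP, n_events, n_alerts.
#' @export
match_events <- function(alerts, events, cfg = match_config()) {
  type_map <- c(rain = "rain_damage", pest = "pest_outbreak",
                rain_damage = "rain_damage", pest_outbreak = "pest_outbreak")
  a_type <- unname(type_map[alerts$alert_type])
  e_type <- unname(type_map[events$event_type])
  types <- sort(unique(c(a_type, e_type)))
  out <- lapply(types, function(ty) {
    A <- alerts[which(a_type == ty), , drop = FALSE]
    E <- events[which(e_type == ty), , drop = FALSE]
    used_alert <- rep(FALSE, nrow(A))
    matched_event <- rep(FALSE, nrow(E))
    if (nrow(E) && nrow(A)) {
      pairs <- expand.grid(e = seq_len(nrow(E)), a = seq_len(nrow(A)))
      pairs$gap <- abs(E$doy[pairs$e] - A$doy[pairs$a])
      pairs <- pairs[E$site_id[pairs$e] == A$site_id[pairs$a] &
                       pairs$gap <= cfg$tp_tolerance_days, , drop = FALSE]
      pairs <- pairs[order(pairs$gap, E$doy[pairs$e]), , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        e <- pairs$e[r]; a <- pairs$a[r]
        if (!matched_event[e] && !used_alert[a]) {
          matched_event[e] <- TRUE
          used_alert[a] <- TRUE
        }
      }
    }
    fp <- 0L
    for (a in seq_len(nrow(A))) {
      near <- nrow(E) > 0 && any(E$site_id == A$site_id[a] &
                                   abs(E$doy - A$doy[a]) <= cfg$fp_exclusion_days)
      if (!near) fp <- fp + 1L
    }
    data.frame(type = ty, TP = sum(matched_event),
               FN = sum(!matched_event), FP = fp,
               n_events = nrow(E), n_alerts = nrow(A),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Alert validation metrics
#'
#' Sensitivity \code{TP / (TP + FN)} as a percentage to one decimal,
#' precision \code{TP / (TP + FP)} to two decimals, and their harmonic-mean
#' F1 (zero by convention when undefined).
#'
#' @param TP,FN,FP Counts.
#' @return List: \code{sensitivity_pct}, \code{precision}, \code{f1}.
#' @export
alert_metrics <- function(TP, FN, FP) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else 0
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  list(sensitivity_pct = round(100 * sens, 1),
       precision = round(prec, 2),
       f1 = round(f1, 2))
}
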