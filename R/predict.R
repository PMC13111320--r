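#' Predict per-interval stages for a site
#'
#' For every interval t in 1..26, classifies the causal pseudo-image built
#' from the series up to t and returns the argmax stage with the four class
#' probabilities.
#'
#' @param model A trained \code{vp_model}.
#' @param series An imputed \code{site_series}.
#' @param norm_params The \code{normalization_params} used in training.
#' @return Data frame: site_id, interval, stage_pred, p_budburst,
#'   p_flowering, p_veraison, p_harvest.
#' @export
predict_stages <- function(model, series, norm_params) {
  X <- t(vapply(seq_len(N_INTERVALS), function(t) {
    as.vector(t(build_pseudo_image(series, t, norm_params)))
  }, numeric(N_INTERVALS * 3L)))
  probs <- model_probs(model, X)
  data.frame(site_id = series$site_id, interval = seq_len(N_INTERVALS),
             stage_pred = STAGES[max.col(probs, ties.method = "first")],
             p_budburst = probs[, 1], p_flowering = probs[, 2],
             p_veraison = probs[, 3], p_harvest = probs[, 4],
             stringsAsFactors = FALSE)
}

#' Extract stage-onset days from a predicted stage sequence
#'
#' The sequence is first monotonized with a running maximum over the stage
#' order (grapevine phenology is sequential); the onset of a stage is the
#' midpoint day of the first interval carrying it. Absent stages get no
#' onset.
#'
#' @param stages Character 26-vector of predicted stages (4 classes).
#' @param season_start_doy Day of year of season day 1.
#' @return Named numeric vector of onset day-of-year values (subset of the
#'   four stages).
#' @export
transitions_from_stages <- function(stages, season_start_doy = 1L) {
  idx <- match(stages, STAGES)
  if (anyNA(idx)) vp_stop("unknown stage label in sequence")
  idx <- cummax(idx)
  onsets <- c()
  for (k in seq_along(STAGES)) {
    first <- which(idx == k)[1]
    if (!is.na(first)) {
      onsets[STAGES[k]] <- interval_midpoint_doy(first, season_start_doy)
    }
  }
  onsets
}
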