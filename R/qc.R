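#' Quality-control configuration
#'
#' @param delta_ndvi_threshold Biweekly NDVI change above which a step is
#'   treated as a non-biological spike (strict inequality; default 0.3).
#' @param drop_fraction Fraction of bad (flagged plus missing) steps above
#'   which a whole series is discarded (strict inequality; default 0.30).
#' @return A \code{qc_config} list.
#' @export
qc_config <- function(delta_ndvi_threshold = 0.3, drop_fraction = 0.30) {
  if (delta_ndvi_threshold <= 0 || delta_ndvi_threshold >= 1) {
    vp_stop("delta_ndvi_threshold must be in (0, 1)")
  }
  if (drop_fraction <= 0 || drop_fraction > 1) {
    vp_stop("drop_fraction must be in (0, 1]")
  }
  structure(list(delta_ndvi_threshold = delta_ndvi_threshold,
                 drop_fraction = drop_fraction), class = "qc_config")
}

#' Flag cloud-like NDVI spikes
#'
#' A change between consecutive observed steps whose magnitude strictly
#' exceeds the threshold marks a spike; since cloud contamination depresses
#' the index, the endpoint with the lower NDVI value is the one flagged.
#' This catches a depressed step both through the drop into it and through
#' the recovery out of it. Changes are computed between consecutive
#' *observed* values, skipping missing steps.
#'
#' @param ndvi Numeric 26-vector, NA for missing.
#' @param cfg A \code{\link{qc_config}}.
#' @return Logical 26-vector, TRUE at flagged steps.
#' @export
flag_spikes <- function(ndvi, cfg = qc_config()) {
  obs <- which(!is.na(ndvi))
  if (length(obs) < 2L) vp_stop("spike filter needs >= 2 observed steps")
  flags <- rep(FALSE, length(ndvi))
  for (k in seq_len(length(obs) - 1L)) {
    a <- obs[k]; b <- obs[k + 1L]
    if (abs(ndvi[b] - ndvi[a]) > cfg$delta_ndvi_threshold) {
      low <- if (ndvi[a] < ndvi[b]) a else b
      flags[low] <- TRUE
    }
  }
  flags
}

#' Partition a collection into kept and dropped series
#'
#' A series is dropped when its flagged plus originally missing steps exceed
#' \code{drop_fraction * 26} (strictly); otherwise the flagged steps are
#' merged into the missing mask (NDVI and EVI censored -- contamination is
#' atmospheric and affects both indices; rainfall is a ground/reanalysis
#' variable and is untouched).
#'
#' @param dataset A \code{vp_dataset}.
#' @param cfg A \code{\link{qc_config}}.
#' @return List with \code{kept} (a \code{vp_dataset} whose series carry a
#'   \code{qc_flags} field and censored indices) and \code{dropped}
#'   (character vector of site ids).
#' @export
qc_partition <- function(dataset, cfg = qc_config()) {
  dropped <- character(0)
  kept <- list()
  for (s in dataset) {
    flags <- flag_spikes(s$ndvi, cfg)
    n_bad <- sum(flags | is.na(s$ndvi))
    if (n_bad > cfg$drop_fraction * N_INTERVALS) {
      dropped <- c(dropped, s$site_id)
      next
    }
    s$qc_flags <- flags
    s$ndvi[flags] <- NA_real_
    s$evi[flags] <- NA_real_
    kept[[length(kept) + 1L]] <- s
  }
  attributes(kept) <- attributes(dataset)[c("seed", "params")]
  class(kept) <- "vp_dataset"
  list(kept = kept, dropped = dropped)
}
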