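#' Imputation configuration
#'
#' Gap-length-adaptive imputation dispatch: length-1 gaps use linear
#' interpolation, lengths 2-3 use cubic-spline interpolation, lengths above 3
#' use LOESS with a span of 0.2 of the series (degree-1 local polynomial,
#' tricube weights) evaluated over a +/- \code{loess_half_window} interval
#' context.
#'
#' @param linear_max_len Max gap length for the linear branch (1).
#' @param spline_max_len Max gap length for the spline branch (3).
#' @param loess_span LOESS span as a fraction of the series (0.2).
#' @param loess_half_window Half-window w in intervals (default 6, so 2w+1 =
#'   13 covers sufficient seasonal context).
#' @return An \code{imputation_config} list.
#' @export
imputation_config <- function(linear_max_len = 1L, spline_max_len = 3L,
                              loess_span = 0.2, loess_half_window = 6L) {
  if (linear_max_len > spline_max_len) {
    vp_stop("linear_max_len must be <= spline_max_len")
  }
  if (loess_span <= 0 || loess_span > 1) vp_stop("loess_span must be in (0,1]")
  structure(list(linear_max_len = linear_max_len,
                 spline_max_len = spline_max_len,
                 loess_span = loess_span,
                 loess_half_window = loess_half_window),
            class = "imputation_config")
}

#' Locate maximal missing runs
#'
#' @param missing Logical 26-vector (TRUE = missing).
#' @return List of \code{gap_segment}s: \code{start}, \code{length},
#'   \code{left_anchor}, \code{right_anchor} (nearest observed indices, NA at
#'   a series edge), ordered by start.
#' @export
find_gaps <- function(missing) {
  stopifnot(is.logical(missing))
  r <- rle(missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- list()
  for (k in which(r$values)) {
    s <- starts[k]; L <- r$lengths[k]
    gaps[[length(gaps) + 1L]] <- structure(list(
      start = s, length = L,
      left_anchor = if (s > 1L) s - 1L else NA_integer_,
      right_anchor = if (s + L <= length(missing)) s + L else NA_integer_
    ), class = "gap_segment")
  }
  gaps
}

# degree-1 LOESS evaluated at gap positions, fitted on observed points
# within +/- w of the gap; the 0.2 span is expressed relative to the whole
# series, so the local neighborhood size is ceil(span * n_observed)
loess_fill <- function(x, gap, cfg) {
  obs <- which(!is.na(x))
  w <- cfg$loess_half_window
  idx <- gap$start:(gap$start + gap$length - 1L)
  win <- obs[obs >= gap$start - w & obs <= gap$start + gap$length - 1L + w]
  while (length(win) < 4L && w < length(x)) {
    w <- w + 1L
    win <- obs[obs >= gap$start - w & obs <= gap$start + gap$length - 1L + w]
  }
  if (length(win) < 4L) {
    vp_stop("too few observed points for LOESS at gap starting ", gap$start)
  }
  q <- max(4L, ceiling(cfg$loess_span * length(obs)))
  span_local <- min(1, q / length(win))
  fit <- stats::loess(y ~ t, data = data.frame(t = win, y = x[win]),
                      span = span_local, degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  stats::predict(fit, newdata = data.frame(t = idx))
}

#' Fill missing steps with the gap-length-adaptive scheme
#'
#' Observed values are never altered. Interior length-1 gaps are linearly
#' interpolated between their anchors; lengths 2-3 use a cubic spline through
#' the observed points (exact on cubic signals); longer gaps use LOESS.
#' Edge gaps with a missing anchor use nearest-observed-value extension for
#' lengths up to 3 and LOESS otherwise.
#'
#' @param x Numeric 26-vector with NA at missing steps.
#' @param gaps Optional list from \code{\link{find_gaps}} (recomputed if
#'   NULL).
#' @param cfg An \code{\link{imputation_config}}.
#' @return Numeric 26-vector with all gaps filled.
#' @export
impute_gaps <- function(x, gaps = NULL, cfg = imputation_config()) {
  if (is.null(gaps)) gaps <- find_gaps(is.na(x))
  if (!length(gaps)) return(x)
  obs <- which(!is.na(x))
  out <- x
  for (g in gaps) {
    idx <- g$start:(g$start + g$length - 1L)
    edge <- is.na(g$left_anchor) || is.na(g$right_anchor)
    if (g$length <= cfg$spline_max_len && edge) {
      anchor <- if (is.na(g$left_anchor)) g$right_anchor else g$left_anchor
      if (is.na(anchor)) vp_stop("series has no observed values")
      out[idx] <- x[anchor]
    } else if (g$length <= cfg$linear_max_len) {
      la <- g$left_anchor; ra <- g$right_anchor
      out[idx] <- x[la] + (x[ra] - x[la]) * (idx - la) / (ra - la)
    } else if (g$length <= cfg$spline_max_len) {
      if (length(obs) < 4L) {
        vp_stop("too few observed points for spline at gap starting ",
                g$start)
      }
      sf <- stats::splinefun(obs, x[obs], method = "fmm")
      out[idx] <- sf(idx)
    } else {
      out[idx] <- loess_fill(x, g, cfg)
    }
  }
  out
}

# which branch handles a gap of length L (exhaustive & exclusive dispatch)
imputation_method_for <- function(L, cfg = imputation_config()) {
  if (L <= cfg$linear_max_len) "linear"
  else if (L <= cfg$spline_max_len) "spline"
  else "loess"
}
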