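#' Inject cloud spikes and missing runs into a site series
#'
#' Emulates the contamination structure of composited satellite vegetation
#' indices: (a) cloud spikes -- selected intervals have NDVI depressed by an
#' amount drawn from N(0.47, 0.12), the empirical depth distribution of
#' confirmed cloud dips (about 94 percent exceed the 0.3 filter threshold);
#' EVI at a contaminated step is depressed proportionally; (b) missing runs
#' whose length classes {1, 2, 3, 4-6, >6} are drawn from \code{gap_mix}.
#' A series is affected by gaps with probability \code{gap_affected_rate};
#' affected series carry 1 + Poisson(0.84) gaps, reproducing the documented
#' dataset-level structure (28.47 percent of series affected, 3.16 percent
#' of timesteps missing) in expectation.
#'
#' Ground truth is recorded in \code{contaminated_steps} (spiked intervals)
#' and \code{gap_steps} (intervals set to NA).
#'
#' @param series A \code{site_series} from \code{\link{simulate_site}}.
#' @param cloud_rate Per-interval spike probability in [0, 1].
#' @param gap_mix Numeric weights over the five gap-length classes
#'   \code{c("1","2","3","4-6",">6")}; must sum to 1 (all-zero disables gaps).
#' @param seed Integer seed.
#' @param gap_affected_rate Probability that a series has any gap.
#' @return The modified \code{site_series}.
#' @export
corrupt_series <- function(series, cloud_rate, gap_mix, seed,
                           gap_affected_rate = 0.2847) {
  if (cloud_rate < 0 || cloud_rate > 1) vp_stop("cloud_rate must be in [0,1]")
  if (length(gap_mix) != 5L) vp_stop("gap_mix needs 5 length-class weights")
  zero_gaps <- all(gap_mix == 0)
  if (!zero_gaps && abs(sum(gap_mix) - 1) > 1e-8) {
    vp_stop("gap_mix weights must sum to 1")
  }
  set.seed(as.integer(seed))

  spiked <- which(stats::runif(N_INTERVALS) < cloud_rate)
  if (length(spiked)) {
    depth <- stats::rnorm(length(spiked), mean = 0.47, sd = 0.12)
    depth <- pmax(0.05, depth)
    series$spike_depth <- stats::setNames(depth, spiked)
    series$ndvi[spiked] <- pmax(-0.2, series$ndvi[spiked] - depth)
    series$evi[spiked] <- pmax(-0.2, series$evi[spiked] - 0.82 * depth)
  }
  series$contaminated_steps <- spiked

  gap_steps <- integer(0)
  if (!zero_gaps && gap_affected_rate > 0 &&
      stats::runif(1) < gap_affected_rate) {
    n_gaps <- 1L + stats::rpois(1, 0.84)
    cls <- sample(5L, n_gaps, replace = TRUE, prob = gap_mix)
    lens <- vapply(cls, function(k) {
      switch(k, 1L, 2L, 3L, sample(4:6, 1L), 7L + stats::rpois(1, 1.5))
    }, integer(1))
    taken <- rep(FALSE, N_INTERVALS)
    for (L in lens) {
      L <- min(L, N_INTERVALS)
      free_starts <- which(vapply(seq_len(N_INTERVALS - L + 1L), function(s) {
        !any(taken[s:(s + L - 1L)])
      }, logical(1)))
      if (!length(free_starts)) next
      s <- free_starts[randi(1L, length(free_starts))]
      taken[s:(s + L - 1L)] <- TRUE
    }
    gap_steps <- which(taken)
    series$ndvi[gap_steps] <- NA_real_
    series$evi[gap_steps] <- NA_real_
  }
  series$gap_steps <- gap_steps
  series
}

#' Default gap-length class mix
#'
#' Gap-count proportions of the documented gap-length distribution
#' (3,842 / 894 / 306 / 142 / 53 gaps in classes 1, 2, 3, 4-6, >6).
#'
#' @return Named numeric vector of 5 weights summing to 1.
#' @export
default_gap_mix <- function() {
  counts <- c("1" = 3842, "2" = 894, "3" = 306, "4-6" = 142, ">6" = 53)
  counts / sum(counts)
}
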