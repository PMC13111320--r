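# Shared fixtures for the test suite.

# small clean dataset (no spikes, no gaps), cached per session
clean_dataset <- local({
  cache <- NULL
  function(n = 60, seed = 11) {
    if (is.null(cache)) {
      cache <<- simulate_dataset(n, seed = seed, cloud_rate = 0,
                                 gap_mix = rep(0, 5), gap_affected_rate = 0)
    }
    cache
  }
})

# tiny architecture for gradient checks and fast training tests
tiny_spec <- function(input_h = 26L) {
  network_spec(input_h = input_h, input_w = 3L, stem_filters = 4L,
               expansion = 2L, block_channels = c(4L, 6L),
               block_strides = c(2L, 2L), final_feature_width = 32L)
}

# flatten a pseudo-image batch the way the training code does
as_input <- function(X) matrix(as.vector(t(X)), ncol = 1)

# small labeled sample set from the cached dataset
small_samples <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- clean_dataset()
      sp <- make_splits(ds, split_plan(seed = 5))
      ids <- vapply(ds, `[[`, "", "site_id")
      tr_ids <- sp$site_id[sp$set == "train" & sp$fold != 1L]
      va_ids <- sp$site_id[sp$set == "train" & sp$fold == 1L]
      pp <- preprocess_dataset(ds[ids %in% tr_ids])
      ppv <- preprocess_dataset(ds[ids %in% va_ids],
                                norm_params = pp$norm_params)
      cache <<- list(
        train = dataset_to_samples(pp$dataset, pp$norm_params, 6L, 1L),
        val = dataset_to_samples(ppv$dataset, pp$norm_params, Inf),
        norm = pp$norm_params,
        train_sites = pp$dataset, val_sites = ppv$dataset)
    }
    cache
  }
})
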