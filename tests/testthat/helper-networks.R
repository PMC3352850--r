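# Shared fixtures: networks are expensive to train, so the suite trains the
# standard consolidated network once and reuses it across test files.

bn_test_cache <- new.env(parent = emptyenv())

cached_standard_network <- function(seed = 1L) {
  key <- paste0("net", seed)
  if (is.null(bn_test_cache[[key]])) {
    bn_test_cache[[key]] <- train_standard_network(seed = seed)
  }
  bn_test_cache[[key]]
}

# A fresh untrained network (cheap; cached for convenience only).
cached_untrained_network <- function(seed = 1L) {
  key <- paste0("raw", seed)
  if (is.null(bn_test_cache[[key]])) {
    bn_test_cache[[key]] <- build_network(seed = seed)
  }
  bn_test_cache[[key]]
}

# Run a batch of trials in test mode and return last motor + recorded counts.
run_test_batch <- function(net, trials, record = character()) {
  neuroburst:::bn_run_batch(net, trials, record = record)
}
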