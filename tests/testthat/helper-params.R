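# Shared fixtures: canonical parameters and noiseless twin, plus a quick
# trial runner used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

canon <- wm_params()
canon0 <- wm_params(noise_sigma = 0)

# run a single fresh-network trial and return the result
quick_trial <- function(params, n_items, probe_item, seed,
                        shuffle_before_probe = FALSE, ...) {
  state <- init_network(params, seed)
  items <- make_items(n_items, params)
  script <- build_trial(items, params, probe_item = probe_item, ...)
  out <- run_trial(state, script, params, record = FALSE,
                   shuffle_before_probe = shuffle_before_probe)
  out$result$items <- items
  out$result
}

# accuracy over independent fresh-network trials
quick_accuracy <- function(params, n_items, probe_item, n, seed0, ...) {
  mean(vapply(seq_len(n), function(i) {
    quick_trial(params, n_items, probe_item, seed0 + 37L * i, ...)$correct
  }, TRUE))
}

encode_one <- function(params, seed, item = NULL) {
  state <- init_network(params, seed)
  item <- item %||% make_items(1L, params)
  res <- run_epoch(state, encode_input(item, params),
                   params$timing$stim, params)
  list(state = res$state, item = item, trace = res$trace,
       units = which(encode_input(item, params) > 0))
}
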