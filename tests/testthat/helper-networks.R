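# Shared trained networks, built once per test run.
#
# short: 5 epochs per emotion — enough for empathy to be established
# (it appears by epoch 2-3 under the default constants) and cheap enough
# for the unit suites. full: the standard 100-epoch schedule, used by the
# acceptance suite.
.net_cache <- new.env(parent = emptyenv())

trained_net_short <- function() {
  if (is.null(.net_cache$short)) {
    res <- train_network(build_network(), schedule = training_schedule(epochs = 5))
    .net_cache$short <- res$net
  }
  .net_cache$short
}

trained_full <- function() {
  if (is.null(.net_cache$full)) {
    .net_cache$full <- train_network(build_network(),
                                     schedule = training_schedule(epochs = 100),
                                     probe = TRUE)
  }
  .net_cache$full
}

# Brute-force all-pairs STDP oracle: explicit nested loops over every
# spike pair, independent of the vectorized implementation path.
apply_stdp_bruteforce <- function(syn, pre, post, params = stdp_params()) {
  w <- syn$weights
  for (i in seq_len(nrow(pre))) {
    for (j in seq_len(nrow(post))) {
      d <- pre$time_ms[i] - post$time_ms[j]
      if (d == 0 || abs(d) > params$window) next
      dw <- if (d < 0) params$A_plus * exp(d / params$tau_plus)
            else -params$A_minus * exp(-d / params$tau_minus)
      r <- pre$neuron_index[i]; c <- post$neuron_index[j]
      w[r, c] <- w[r, c] + dw
    }
  }
  w <- pmin(pmax(w, params$w_min), params$w_max)
  w * syn$mask
}
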