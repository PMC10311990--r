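# Shared fixture builders: everything is generated in code at test time.

# Raster from a dense 0/1 matrix (neurons x bins), one trial.
raster_from_matrix <- function(mat, dt = 1) {
  hits <- which(mat == 1L, arr.ind = TRUE)
  spike_raster(data.frame(neuron = hits[, 1], trial = 1L, bin = hits[, 2]),
               n_neurons = nrow(mat), n_trials = 1L,
               trial_duration = ncol(mat) * dt, dt = dt)
}

# Repeat a set of input patterns (columns of `patterns`) `times` times and
# label each bin with a linear threshold rule -- a small separable problem.
pattern_problem <- function(patterns, w_true, threshold, times = 20) {
  mat <- patterns[, rep(seq_len(ncol(patterns)), times), drop = FALSE]
  y <- as.integer(crossprod(mat, w_true) > threshold)
  list(raster = raster_from_matrix(mat), y = y)
}

# Small hyperactive population with known feedforward weights. The spike
# threshold scales with population size; small fixtures use a lower one so
# the postsynaptic unit fires often enough to learn from.
hyper_fixture <- function(n = 60, n_conn = 30, n_exc = 24, trials = 100,
                          dur = 500, seed = 1, threshold = 10) {
  w <- build_feedforward_weights(n, n_conn, n_exc, seed = seed)
  spec <- population_spec(n, silent_fraction = 0)
  r <- generate_raster(spec, trials, dur, seed = seed + 100)
  list(w = w, raster = r, y = threshold_forward(r, w, threshold),
       threshold = threshold)
}
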