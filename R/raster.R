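#' Describe the composition of a presynaptic population
#'
#' A population mixes "silent" neurons, firing at around one spike per minute,
#' with active neurons. Rates are either fixed per subgroup
#' (`rate_law = "uniform_fixed"`) or drawn from a lognormal distribution
#' parameterized by its mean and SD in Hz (`rate_law = "lognormal"`,
#' moment-matched to the underlying normal).
#'
#' @param n_total number of presynaptic spike trains.
#' @param silent_fraction proportion of the population that is silent, in
#'   `[0, 1]`. Default 0.66, as observed in motor cortex.
#' @param silent_rate firing rate of silent neurons in Hz (default 0.017,
#'   i.e. ~1 spike/min).
#' @param active_rate firing rate of active neurons in Hz (default 20).
#' @param rate_law `"uniform_fixed"` (two fixed rates) or `"lognormal"`.
#' @param lognormal_mean,lognormal_sd mean and SD in Hz of the lognormal rate
#'   distribution, used when `rate_law = "lognormal"` (defaults 3.7 and 3.5).
#' @return An object of class `"population_spec"`.
#' @export
#' @examples
#' population_spec(200)
population_spec <- function(n_total, silent_fraction = 0.66,
                            silent_rate = 0.017, active_rate = 20,
                            rate_law = c("uniform_fixed", "lognormal"),
                            lognormal_mean = 3.7, lognormal_sd = 3.5) {
  rate_law <- match.arg(rate_law)
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1)
    stop_field("n_total", "must be a single count >= 1")
  if (!is.numeric(silent_fraction) || silent_fraction < 0 || silent_fraction > 1)
    stop_field("silent_fraction", "must lie in [0, 1]")
  if (silent_rate < 0) stop_field("silent_rate", "must be >= 0")
  if (active_rate < 0) stop_field("active_rate", "must be >= 0")
  if (rate_law == "lognormal" && (lognormal_mean <= 0 || lognormal_sd <= 0))
    stop_field("lognormal_mean", "lognormal mean and sd must be > 0")
  structure(list(n_total = as.integer(n_total),
                 silent_fraction = silent_fraction,
                 silent_rate = silent_rate, active_rate = active_rate,
                 rate_law = rate_law, lognormal_mean = lognormal_mean,
                 lognormal_sd = lognormal_sd),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population spec:", x$n_total, "neurons\n")
  if (x$rate_law == "uniform_fixed") {
    n_silent <- round(x$n_total * x$silent_fraction)
    cat(sprintf("  %d silent at %g Hz, %d active at %g Hz\n",
                n_silent, x$silent_rate, x$n_total - n_silent, x$active_rate))
  } else {
    cat(sprintf("  lognormal rates, mean %g Hz, sd %g Hz\n",
                x$lognormal_mean, x$lognormal_sd))
  }
  invisible(x)
}

# Nominal per-neuron rates implied by a population spec. Silent neurons
# occupy the tail of the index range.
population_rates <- function(spec, seed = NULL) {
  if (spec$rate_law == "uniform_fixed") {
    n_silent <- round(spec$n_total * spec$silent_fraction)
    c(rep(spec$active_rate, spec$n_total - n_silent),
      rep(spec$silent_rate, n_silent))
  } else {
    with_seed(seed, rlnorm_moments(spec$n_total, spec$lognormal_mean,
                                   spec$lognormal_sd))
  }
}

# Lognormal draws parameterized by the distribution's own mean and SD.
rlnorm_moments <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Construct a spike raster
#'
#' A raster is a sparse binary occupancy structure over
#' (neuron, trial, time bin): `events` lists every spike once. Bins are
#' `dt`-ms wide; `trial_duration / dt` must be an integer.
#'
#' @param events data frame with integer columns `neuron` (1-based),
#'   `trial` (1-based) and `bin` (1-based within trial).
#' @param n_neurons,n_trials,trial_duration,dt raster dimensions;
#'   `trial_duration` and `dt` in ms (dt default 1).
#' @param meta optional list of generation metadata carried along.
#' @param validate check event ranges and uniqueness (skipped by internal
#'   generators whose construction guarantees both).
#' @return An object of class `"spike_raster"`.
#' @export
spike_raster <- function(events, n_neurons, n_trials, trial_duration, dt = 1,
                         meta = list(), validate = TRUE) {
  if (trial_duration <= 0 || dt <= 0)
    stop_field("trial_duration", "durations must be positive")
  n_bins <- trial_duration / dt
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop_field("trial_duration", "must be divisible by dt")
  n_bins <- as.integer(round(n_bins))
  events <- data.frame(neuron = as.integer(events$neuron),
                       trial = as.integer(events$trial),
                       bin = as.integer(events$bin))
  if (validate && nrow(events)) {
    if (anyNA(events)) stop_field("events", "contains NA")
    if (min(events$neuron) < 1L || max(events$neuron) > n_neurons)
      stop_field("events", "neuron id out of range")
    if (min(events$trial) < 1L || max(events$trial) > n_trials)
      stop_field("events", "trial out of range")
    if (min(events$bin) < 1L || max(events$bin) > n_bins)
      stop_field("events", "bin out of range")
    key <- (events$neuron - 1) * (as.numeric(n_trials) * n_bins) +
      (events$trial - 1) * as.numeric(n_bins) + events$bin
    if (anyDuplicated(key))
      stop_field("events", "duplicate spikes (occupancy must be 0/1)")
  }
  structure(list(events = events, n_neurons = as.integer(n_neurons),
                 n_trials = as.integer(n_trials),
                 trial_duration = trial_duration, dt = dt,
                 n_bins = n_bins, meta = meta),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d neurons, %d trials x %g ms (dt = %g ms)\n",
              x$n_neurons, x$n_trials, x$trial_duration, x$dt))
  cat(sprintf("  %d spikes, population mean rate %.3g Hz\n",
              nrow(x$events), mean(firing_rates(x))))
  invisible(x)
}

#' @export
summary.spike_raster <- function(object, ...) {
  r <- firing_rates(object)
  out <- list(raster = object, rates = r)
  class(out) <- "summary.spike_raster"
  out
}

#' @export
print.summary.spike_raster <- function(x, ...) {
  print(x$raster)
  cat("Per-neuron empirical rates (Hz):\n")
  print(summary(x$rates))
  invisible(x)
}

#' Per-neuron empirical firing rates of a raster, in Hz
#'
#' @param raster a [spike_raster()].
#' @return Numeric vector of length `n_neurons`.
#' @export
firing_rates <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  total_s <- raster$n_trials * raster$trial_duration / 1000
  tabulate(raster$events$neuron, nbins = raster$n_neurons) / total_s
}

#' @export
as.matrix.spike_raster <- function(x, ...) {
  # dense (neuron x total-bin) occupancy; intended for small rasters
  nb <- as.numeric(x$n_trials) * x$n_bins
  if (x$n_neurons * nb > 5e7)
    stop("raster too large to densify; work with $events instead")
  m <- matrix(0L, x$n_neurons, nb)
  g <- (x$events$trial - 1) * x$n_bins + x$events$bin
  m[cbind(x$events$neuron, g)] <- 1L
  m
}

# Global trial-major bin index of each event (1-based).
global_bins <- function(raster) {
  (raster$events$trial - 1) * raster$n_bins + raster$events$bin
}

# CSR index over global bins for the C++ kernels.
raster_csr <- function(raster) {
  nb_total <- raster$n_trials * raster$n_bins
  bin_events_cpp(as.integer(global_bins(raster)), raster$events$neuron,
                 as.integer(nb_total))
}

# Vectorized sparse Bernoulli sampler: for each of n units, draw per-bin
# spikes over n_bins bins with per-unit probability p (binomial count +
# uniform placement without replacement, equivalent to i.i.d. Bernoulli bins).
sample_spike_bins <- function(p, n_bins) {
  n <- length(p)
  counts <- rbinom(n, n_bins, pmin(1, p))
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    if (counts[i] > 0) pos[[i]] <- sample.int(n_bins, counts[i])
  }
  list(unit = rep.int(seq_len(n), counts), pos = unlist(pos))
}

#' Generate a population spike raster
#'
#' Each neuron with nominal rate f spikes independently in every dt-ms bin
#' with probability `min(1, f * dt / 1000)`, so empirical rates converge to
#' nominal rates as total duration grows.
#'
#' @param spec a [population_spec()].
#' @param n_trials number of trials.
#' @param trial_duration trial length in ms.
#' @param dt bin width in ms (default 1).
#' @param seed RNG seed; a given seed fully determines the raster.
#' @return A [spike_raster()] whose `meta` records the nominal rates.
#' @export
#' @examples
#' r <- generate_raster(population_spec(20), n_trials = 5,
#'                      trial_duration = 1000, seed = 1)
#' firing_rates(r)
generate_raster <- function(spec, n_trials, trial_duration, dt = 1,
                            seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (n_trials < 1) stop_field("n_trials", "must be >= 1")
  with_seed(seed, {
    rates <- population_rates(spec)
    n_bins <- as.integer(round(trial_duration / dt))
    total_bins <- n_trials * n_bins
    sm <- sample_spike_bins(rates * dt / 1000, total_bins)
    events <- data.frame(
      neuron = sm$unit,
      trial = if (length(sm$pos)) (sm$pos - 1L) %/% n_bins + 1L else integer(),
      bin = if (length(sm$pos)) (sm$pos - 1L) %% n_bins + 1L else integer())
    spike_raster(events, spec$n_total, n_trials, trial_duration, dt,
                 meta = list(rates = rates, spec = spec), validate = FALSE)
  })
}

#' Synthesize a surrogate multichannel recording
#'
#' Emulates a multichannel extracellular recording as a single-trial raster:
#' channels fire at lognormally distributed baseline rates, multiplied by
#' `stim_gain` during an initial stimulation epoch. Defaults mirror a
#' 64-channel, 900-s session opening with a 60-s elevated-rate epoch.
#'
#' @param n_channels number of recorded units (default 64).
#' @param total_duration total duration in seconds (default 900).
#' @param stim_epoch_duration initial stimulation epoch in seconds
#'   (default 60); must not exceed `total_duration`.
#' @param baseline_rates optional per-channel baseline rates in Hz; drawn
#'   from a lognormal law with mean `lognormal_mean`, SD `lognormal_sd`
#'   when `NULL`.
#' @param lognormal_mean,lognormal_sd Hz moments of the baseline-rate law
#'   (defaults 3.7 and 3.5).
#' @param stim_gain rate multiplier inside the epoch (default 3).
#' @param dt bin width in ms.
#' @param seed RNG seed.
#' @return A single-trial [spike_raster()]; `meta$baseline_rates` and
#'   `meta$stim_epoch_bins` record the generation parameters.
#' @export
generate_surrogate_recording <- function(n_channels = 64,
                                         total_duration = 900,
                                         stim_epoch_duration = 60,
                                         baseline_rates = NULL,
                                         lognormal_mean = 3.7,
                                         lognormal_sd = 3.5,
                                         stim_gain = 3, dt = 1,
                                         seed = NULL) {
  if (total_duration <= 0 || stim_epoch_duration < 0)
    stop_field("total_duration", "durations must be positive")
  if (stim_epoch_duration > total_duration)
    stop_field("stim_epoch_duration", "must not exceed total_duration")
  with_seed(seed, {
    if (is.null(baseline_rates))
      baseline_rates <- rlnorm_moments(n_channels, lognormal_mean,
                                       lognormal_sd)
    stopifnot(length(baseline_rates) == n_channels)
    bins_total <- as.integer(round(total_duration * 1000 / dt))
    bins_stim <- as.integer(round(stim_epoch_duration * 1000 / dt))
    ev_stim <- sample_spike_bins(stim_gain * baseline_rates * dt / 1000,
                                 bins_stim)
    ev_base <- sample_spike_bins(baseline_rates * dt / 1000,
                                 bins_total - bins_stim)
    events <- data.frame(
      neuron = c(ev_stim$unit, ev_base$unit),
      trial = 1L,
      bin = c(ev_stim$pos,
              if (length(ev_base$pos)) ev_base$pos + bins_stim else integer()))
    spike_raster(events, n_channels, 1L, total_duration * 1000, dt,
                 meta = list(baseline_rates = baseline_rates,
                             stim_epoch_bins = bins_stim,
                             stim_gain = stim_gain),
                 validate = FALSE)
  })
}

#' Read and write rasters as delimited event lists
#'
#' The on-disk format is tab-separated text with a `#`-comment header line
#' carrying the raster dimensions, then columns `neuron_id` (0-based),
#' `trial` (0-based) and `time_ms` (0-based bin index). The round trip is
#' lossless.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `read_raster` returns a [spike_raster()]; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spike_raster n_neurons=%d n_trials=%d trial_duration=%g dt=%g",
                     raster$n_neurons, raster$n_trials,
                     raster$trial_duration, raster$dt), con)
  writeLines("neuron_id\ttrial\ttime_ms", con)
  ev <- raster$events
  if (nrow(ev)) {
    write.table(data.frame(ev$neuron - 1L, ev$trial - 1L, ev$bin - 1L),
                con, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# spike_raster"))
    stop("not a spike_raster event-list file")
  fields <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.eE+-]+", hdr))[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  ev <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spike_raster(data.frame(neuron = ev$neuron_id + 1L, trial = ev$trial + 1L,
                          bin = ev$time_ms + 1L),
               n_neurons = vals[["n_neurons"]], n_trials = vals[["n_trials"]],
               trial_duration = vals[["trial_duration"]], dt = vals[["dt"]])
}

# Coerce a postsynaptic spike argument (binary vector in trial-major bin
# order, or a single-neuron raster) to an integer 0/1 vector.
as_spike_train <- function(post, n_bins_total) {
  if (inherits(post, "spike_raster")) {
    if (post$n_neurons != 1L)
      stop("postsynaptic raster must contain exactly one neuron")
    y <- integer(post$n_trials * post$n_bins)
    y[global_bins(post)] <- 1L
    post <- y
  }
  post <- as.integer(post)
  if (!all(post %in% c(0L, 1L))) stop("spike train must be binary")
  if (!missing(n_bins_total) && length(post) != n_bins_total)
    stop("spike train length does not match raster bins")
  post
}
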