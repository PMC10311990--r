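#' Describe a stimulation protocol
#'
#' A protocol drives subsets of cells at an elevated rate during short
#' epochs. Defaults follow common practice: 50 cells at 60 Hz for 200 ms.
#' `n_stimulations` counts the distinct stimulation events; with
#' `selection_rule = "resample_each_epoch"` each event targets a fresh
#' random cell subset (the setting under which population coverage grows as
#' `1 - (1 - m/N)^k`).
#'
#' Two placement modes are supported:
#' \describe{
#'   \item{`"per_trial"` (default)}{Every trial presents one stimulation
#'     event as a 200-ms epoch at a fixed latency, the k events cycling
#'     round-robin across trials -- the usual per-trial stimulus
#'     presentation design. This is the mode under which repeated
#'     presentations accumulate enough driven spikes per silent cell for
#'     weight derivation.}
#'   \item{`"designated"`}{Each event occupies a single epoch in one
#'     designated trial, designated trials spread evenly over the trial
#'     set. Stimulation then amounts to k isolated epochs in the whole
#'     recording, the natural bookkeeping for rate-vs-stimulus-count
#'     scaling analyses.}
#' }
#'
#' @param n_stimulations number of stimulation events (0 = none).
#' @param n_stimulated_cells cells driven per event (default 50).
#' @param stim_rate driven firing rate in Hz (default 60).
#' @param stim_duration epoch length in ms (default 200).
#' @param selection_rule `"resample_each_epoch"` (fresh random subset per
#'   event) or `"fixed_subset"` (one subset reused by every event).
#' @param cells optional explicit cell ids (1-based) for
#'   `selection_rule = "fixed_subset"`.
#' @param placement_mode `"per_trial"` or `"designated"`, see Details.
#' @param onset epoch onset within a trial, ms from trial start (default 0).
#' @param placement optional data frame with columns `trial` (1-based) and
#'   `onset` (0-based bin offset), one row per event; overrides
#'   `placement_mode = "designated"` placement.
#' @return An object of class `"stimulation_protocol"`.
#' @export
#' @examples
#' stimulation_protocol(15)
stimulation_protocol <- function(n_stimulations,
                                 n_stimulated_cells = 50,
                                 stim_rate = 60, stim_duration = 200,
                                 selection_rule = c("resample_each_epoch",
                                                    "fixed_subset"),
                                 cells = NULL,
                                 placement_mode = c("per_trial",
                                                    "designated"),
                                 onset = 0, placement = NULL) {
  selection_rule <- match.arg(selection_rule)
  placement_mode <- match.arg(placement_mode)
  if (n_stimulations < 0) stop_field("n_stimulations", "must be >= 0")
  if (n_stimulated_cells < 1) stop_field("n_stimulated_cells", "must be >= 1")
  if (stim_rate < 0) stop_field("stim_rate", "must be >= 0")
  if (stim_duration <= 0) stop_field("stim_duration", "must be > 0")
  if (onset < 0) stop_field("onset", "must be >= 0")
  if (!is.null(cells)) {
    cells <- as.integer(cells)
    if (length(cells) != n_stimulated_cells)
      stop_field("cells", "length must equal n_stimulated_cells")
  }
  if (!is.null(placement)) {
    stopifnot(all(c("trial", "onset") %in% names(placement)))
    if (nrow(placement) != n_stimulations)
      stop_field("placement", "needs one row per stimulation event")
    placement_mode <- "designated"
  }
  structure(list(n_stimulations = as.integer(n_stimulations),
                 n_stimulated_cells = as.integer(n_stimulated_cells),
                 stim_rate = stim_rate, stim_duration = stim_duration,
                 selection_rule = selection_rule, cells = cells,
                 placement_mode = placement_mode, onset = onset,
                 placement = placement),
            class = "stimulation_protocol")
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol: %d event(s), %d cells at %g Hz for %g ms\n",
              x$n_stimulations, x$n_stimulated_cells, x$stim_rate,
              x$stim_duration))
  cat(sprintf("  %s placement, %s\n", x$placement_mode, x$selection_rule))
  invisible(x)
}

# Designated-mode placement: one epoch per designated trial, onset 0,
# designated trials spread evenly over the trial set.
default_placement <- function(n_stimulations, n_trials) {
  if (n_stimulations > n_trials)
    stop_field("n_stimulations", "exceeds the number of trials")
  trials <- if (n_stimulations == 1L) 1L else
    floor(seq(0, n_trials - 1, length.out = n_stimulations)) + 1L
  data.frame(trial = as.integer(trials), onset = 0L)
}

#' Apply a stimulation protocol to a raster
#'
#' Within each epoch window the selected cells' bins are regenerated as
#' independent Bernoulli draws at the stimulation rate, replacing whatever
#' baseline spikes were there; every bin outside the epoch windows (and
#' every unselected cell) is returned unchanged.
#'
#' @param raster a [spike_raster()].
#' @param protocol a [stimulation_protocol()].
#' @param seed RNG seed governing both cell selection and resampled spikes.
#' @return A list with elements `raster` (the stimulated [spike_raster()])
#'   and `stimulated_sets` (a list of the per-event selected cell-id sets,
#'   for coverage accounting).
#' @export
#' @examples
#' r <- generate_raster(population_spec(100), 10, 1000, seed = 1)
#' s <- apply_stimulation(r, stimulation_protocol(2, 10), seed = 2)
#' length(s$stimulated_sets)
apply_stimulation <- function(raster, protocol, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(protocol, "stimulation_protocol"))
  if (protocol$n_stimulations == 0L)
    return(list(raster = raster, stimulated_sets = list()))
  if (protocol$n_stimulated_cells > raster$n_neurons)
    stop_field("n_stimulated_cells", "exceeds the raster population")
  L <- protocol$stim_duration / raster$dt
  if (abs(L - round(L)) > 1e-9)
    stop_field("stim_duration", "must be divisible by raster dt")
  L <- as.integer(round(L))
  onset_bins <- as.integer(round(protocol$onset / raster$dt))
  if (onset_bins + L > raster$n_bins)
    stop_field("stim_duration", "epoch exceeds trial bounds")

  with_seed(seed, {
    k <- protocol$n_stimulations
    sets <- vector("list", k)
    for (i in seq_len(k)) {
      sets[[i]] <- if (protocol$selection_rule == "fixed_subset") {
        if (i == 1L) {
          if (!is.null(protocol$cells)) sort(protocol$cells) else
            sort(sample.int(raster$n_neurons, protocol$n_stimulated_cells))
        } else sets[[1L]]
      } else sort(sample.int(raster$n_neurons,
                             protocol$n_stimulated_cells))
    }
    out <- if (protocol$placement_mode == "per_trial")
      stimulate_per_trial(raster, protocol, sets, L, onset_bins)
    else
      stimulate_designated(raster, protocol, sets, L)
    list(raster = out, stimulated_sets = sets)
  })
}

# Per-trial mode: trial t presents pattern ((t-1) mod k) + 1 in the window
# [onset, onset + L). Patterns partition trials, so all replacements can be
# computed in one pass.
stimulate_per_trial <- function(raster, protocol, sets, L, onset_bins) {
  k <- length(sets)
  if (k > raster$n_trials)
    stop_field("n_stimulations", "exceeds the number of trials")
  pat_of_trial <- (seq_len(raster$n_trials) - 1L) %% k + 1L
  member <- matrix(FALSE, k, raster$n_neurons)
  for (i in seq_len(k)) member[i, sets[[i]]] <- TRUE
  ev <- raster$events
  lo <- onset_bins + 1L
  hi <- onset_bins + L
  drop <- ev$bin >= lo & ev$bin <= hi &
    member[cbind(pat_of_trial[ev$trial], ev$neuron)]
  p_stim <- min(1, protocol$stim_rate * raster$dt / 1000)
  new_ev <- vector("list", k)
  for (i in seq_len(k)) {
    trials_i <- which(pat_of_trial == i)
    m <- length(sets[[i]])
    n_units <- m * length(trials_i)
    if (n_units == 0) next
    sm <- sample_spike_bins(rep(p_stim, n_units), L)
    if (length(sm$pos)) {
      cell_idx <- (sm$unit - 1L) %% m + 1L
      trial_idx <- (sm$unit - 1L) %/% m + 1L
      new_ev[[i]] <- data.frame(neuron = sets[[i]][cell_idx],
                                trial = trials_i[trial_idx],
                                bin = sm$pos + onset_bins)
    }
  }
  events <- rbind(ev[!drop, , drop = FALSE], do.call(rbind, new_ev))
  spike_raster(events, raster$n_neurons, raster$n_trials,
               raster$trial_duration, raster$dt,
               meta = c(raster$meta, list(protocol = protocol)),
               validate = FALSE)
}

# Designated mode: k isolated epochs, one per designated trial. Edited
# sequentially over the (small) designated-trial slice so stacked custom
# placements compose correctly.
stimulate_designated <- function(raster, protocol, sets, L) {
  placement <- protocol$placement
  if (is.null(placement))
    placement <- default_placement(protocol$n_stimulations, raster$n_trials)
  if (any(placement$trial < 1 | placement$trial > raster$n_trials) ||
      any(placement$onset < 0 | placement$onset + L > raster$n_bins))
    stop_field("placement", "epoch exceeds trial bounds")
  ev <- raster$events
  touched <- ev$trial %in% placement$trial
  sub <- ev[touched, , drop = FALSE]
  p_stim <- min(1, protocol$stim_rate * raster$dt / 1000)
  for (i in seq_along(sets)) {
    set <- sets[[i]]
    tr <- placement$trial[i]
    lo <- placement$onset[i] + 1L
    hi <- placement$onset[i] + L
    drop <- sub$trial == tr & sub$bin >= lo & sub$bin <= hi &
      sub$neuron %in% set
    sm <- sample_spike_bins(rep(p_stim, length(set)), L)
    new_ev <- if (length(sm$pos))
      data.frame(neuron = set[sm$unit], trial = tr,
                 bin = sm$pos + placement$onset[i]) else NULL
    sub <- rbind(sub[!drop, , drop = FALSE], new_ev)
  }
  events <- rbind(ev[!touched, , drop = FALSE], sub)
  spike_raster(events, raster$n_neurons, raster$n_trials,
               raster$trial_duration, raster$dt,
               meta = c(raster$meta, list(protocol = protocol,
                                          placement = placement)),
               validate = FALSE)
}
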