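#' Run a replicated feedforward derivation experiment
#'
#' End-to-end pipeline for one study condition: per replicate, build a
#' ground-truth feedforward weight vector, generate a population raster,
#' optionally apply a stimulation protocol, simulate the actual
#' postsynaptic spikes with the threshold unit, derive weights with
#' [perceptron_fit()], and evaluate weight recovery and spike prediction
#' on freshly generated held-out test trials (stimulated condition by
#' default, matching how prediction is validated). A master seed fans out
#' to per-replicate, per-stage sub-seeds via [child_seed()].
#'
#' Conditions: `"hyperactive"` (no silent neurons, all at the active
#' rate), `"silent_unstimulated"` (66% silent, no stimulation),
#' `"silent_stimulated"` (66% silent plus the stimulation protocol) and
#' `"single_silent_perturbation"` (silent population in which the single
#' strongest excitatory silent cell is driven in every epoch).
#'
#' @param condition study condition, see Details.
#' @param n_replicates randomized populations (default 10).
#' @param master_seed integer master seed.
#' @param n_population population size (default 200).
#' @param silent_fraction,silent_rate,active_rate population composition
#'   for the silent conditions (defaults 0.66, 0.017 Hz, 20 Hz).
#' @param n_connected,n_excitatory,weight_range ground-truth connectivity
#'   (defaults 100, 80, `c(-8, 8)` mV).
#' @param n_trials,trial_duration training data size (defaults 2500 trials
#'   of 1000 ms).
#' @param n_stimulations,n_stimulated_cells,stim_rate,stim_duration
#'   stimulation protocol (defaults 15 epochs, 50 cells, 60 Hz, 200 ms).
#' @param lr,iterations perceptron training (defaults 0.01, 100).
#' @param threshold threshold-unit spike threshold (mV).
#' @param n_test_trials held-out test trials (default `n_trials`); 0 skips
#'   the prediction evaluation (tpr/ppv reported as `NA`).
#' @param test_stimulated generate test data under the stimulated
#'   condition (default TRUE).
#' @param scheme a [classification_scheme()].
#' @param keep_weights keep per-replicate derived/actual weight vectors in
#'   the result (needed by [calibrate_epsilon()]; default TRUE).
#' @return An object of class `"feedforward_experiment"`: list with
#'   `condition`, `replicates` (per-replicate data frame of rmse, pearson
#'   r, tpr, ppv, performance), `per_class_rmse` and `per_class_accuracy`
#'   (replicate x class matrices), `aggregate` (mean and SE per measure)
#'   and `runs` (per-replicate weight vectors).
#' @export
#' @examples
#' ex <- run_feedforward_experiment("hyperactive", n_replicates = 2,
#'                                  n_population = 50, n_connected = 25,
#'                                  n_excitatory = 20, n_trials = 50,
#'                                  trial_duration = 500, iterations = 10,
#'                                  master_seed = 1)
#' ex$aggregate
run_feedforward_experiment <- function(condition = c("hyperactive",
                                                     "silent_unstimulated",
                                                     "silent_stimulated",
                                                     "single_silent_perturbation"),
                                       n_replicates = 10, master_seed = 1,
                                       n_population = 200,
                                       silent_fraction = 0.66,
                                       silent_rate = 0.017,
                                       active_rate = 20,
                                       n_connected = 100, n_excitatory = 80,
                                       weight_range = c(-8, 8),
                                       n_trials = 2500,
                                       trial_duration = 1000,
                                       n_stimulations = 15,
                                       n_stimulated_cells = 50,
                                       stim_rate = 60, stim_duration = 200,
                                       lr = 0.01, iterations = 100,
                                       threshold = 20,
                                       n_test_trials = n_trials,
                                       test_stimulated = TRUE,
                                       scheme = classification_scheme(),
                                       keep_weights = TRUE) {
  condition <- match.arg(condition)
  if (n_replicates < 1) stop_field("n_replicates", "must be >= 1")
  spec <- population_spec(
    n_population,
    silent_fraction = if (condition == "hyperactive") 0 else silent_fraction,
    silent_rate = silent_rate, active_rate = active_rate)
  test_protocol <- stimulation_protocol(n_stimulations, n_stimulated_cells,
                                        stim_rate, stim_duration)
  reps <- vector("list", n_replicates)
  runs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- function(stage) child_seed(master_seed, r, stage)
    w_true <- build_feedforward_weights(n_population, n_connected,
                                        n_excitatory, weight_range,
                                        seed = s(1))
    raster <- generate_raster(spec, n_trials, trial_duration, seed = s(2))
    if (condition == "silent_stimulated") {
      raster <- apply_stimulation(raster, test_protocol, seed = s(3))$raster
    } else if (condition == "single_silent_perturbation") {
      n_silent <- round(n_population * spec$silent_fraction)
      silent_ids <- seq.int(n_population - n_silent + 1L, n_population)
      target <- silent_ids[which.max(w_true[silent_ids])]
      prot <- stimulation_protocol(n_stimulations, 1, stim_rate,
                                   stim_duration,
                                   selection_rule = "fixed_subset",
                                   cells = target)
      raster <- apply_stimulation(raster, prot, seed = s(3))$raster
    }
    y <- threshold_forward(raster, w_true, threshold)
    fit <- perceptron_fit(raster, y, model = "threshold", lr = lr,
                          iterations = iterations, actual = w_true,
                          threshold = threshold)
    if (n_test_trials > 0) {
      test <- generate_raster(spec, n_test_trials, trial_duration,
                              seed = s(4))
      if (test_stimulated)
        test <- apply_stimulation(test, test_protocol, seed = s(5))$raster
      y_test <- threshold_forward(test, w_true, threshold)
      rep_eval <- evaluate_run(coef(fit), w_true, y_test,
                               predict(fit, test), scheme)
    } else {
      rep_eval <- evaluate_run(coef(fit), w_true, scheme = scheme)
    }
    reps[[r]] <- rep_eval
    if (keep_weights)
      runs[[r]] <- list(derived = coef(fit), actual = w_true,
                        performance = rep_eval$performance)
  }
  assemble_ff_experiment(condition, reps, runs)
}

# Shared assembly of per-replicate evaluation reports into the classed
# experiment object with mean/SE aggregates.
assemble_ff_experiment <- function(condition, reps, runs = NULL) {
  replicates <- data.frame(
    replicate = seq_along(reps),
    rmse = vapply(reps, `[[`, 1, "rmse_weights"),
    pearson_r = vapply(reps, `[[`, 1, "pearson_r"),
    tpr = vapply(reps, function(x) x$tpr %||% NA_real_, 1),
    ppv = vapply(reps, function(x) x$ppv %||% NA_real_, 1),
    performance = vapply(reps, function(x) x$performance %||% NA_real_, 1))
  per_class_rmse <- do.call(rbind, lapply(reps, `[[`, "per_class_rmse"))
  per_class_accuracy <- do.call(rbind,
                                lapply(reps, `[[`, "per_class_accuracy"))
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), se = std_err(v))
  measures <- replicates[, c("rmse", "pearson_r", "tpr", "ppv",
                             "performance")]
  structure(list(condition = condition, replicates = replicates,
                 per_class_rmse = per_class_rmse,
                 per_class_accuracy = per_class_accuracy,
                 aggregate = vapply(measures, agg, c(mean = 1, se = 1)),
                 runs = runs),
            class = "feedforward_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SE of the mean: sample SD / sqrt(n over non-missing replicates).
std_err <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2) return(NA_real_)
  sd(v) / sqrt(length(v))
}

#' @export
print.feedforward_experiment <- function(x, ...) {
  cat(sprintf("Feedforward experiment [%s], %d replicates\n",
              x$condition, nrow(x$replicates)))
  a <- x$aggregate
  cat(sprintf("  weight RMSE %.3f +/- %.3f mV, Pearson r %.3f +/- %.3f\n",
              a["mean", "rmse"], a["se", "rmse"],
              a["mean", "pearson_r"], a["se", "pearson_r"]))
  if (!all(is.na(x$replicates$tpr)))
    cat(sprintf("  spike prediction: TPR %.3f +/- %.3f, PPV %.3f +/- %.3f\n",
                a["mean", "tpr"], a["se", "tpr"],
                a["mean", "ppv"], a["se", "ppv"]))
  invisible(x)
}

#' Sweep the number of stimulation epochs
#'
#' Runs the silent-population derivation across stimulus counts with a
#' paired design: every count reuses the same per-replicate ground truth,
#' baseline raster, stimulation seed and held-out test data, so count 0
#' reproduces the unstimulated baseline exactly and differences across
#' counts are attributable to stimulation alone.
#'
#' @inheritParams run_feedforward_experiment
#' @param stimulus_counts epoch counts to sweep (default 0:15).
#' @return An object of class `"stimulus_sweep"`: list with `by_count`
#'   (per-count aggregate data frame), `rmse` (replicate x count matrix),
#'   `per_class_rmse` and `per_class_accuracy` (count x class mean
#'   matrices) and `counts`.
#' @export
run_stimulus_sweep <- function(stimulus_counts = 0:15, n_replicates = 10,
                               master_seed = 1, n_population = 200,
                               silent_fraction = 0.66, silent_rate = 0.017,
                               active_rate = 20, n_connected = 100,
                               n_excitatory = 80, weight_range = c(-8, 8),
                               n_trials = 2500, trial_duration = 1000,
                               n_stimulated_cells = 50, stim_rate = 60,
                               stim_duration = 200, lr = 0.01,
                               iterations = 100, threshold = 20,
                               n_test_trials = n_trials,
                               scheme = classification_scheme()) {
  spec <- population_spec(n_population, silent_fraction = silent_fraction,
                          silent_rate = silent_rate,
                          active_rate = active_rate)
  test_protocol <- stimulation_protocol(max(max(stimulus_counts), 1),
                                        n_stimulated_cells, stim_rate,
                                        stim_duration)
  nk <- length(stimulus_counts)
  rmse <- matrix(NA_real_, n_replicates, nk)
  tpr <- ppv <- pearson <- rmse
  pcr <- pca <- array(NA_real_, c(n_replicates, nk, 5))
  for (r in seq_len(n_replicates)) {
    s <- function(stage) child_seed(master_seed, r, stage)
    w_true <- build_feedforward_weights(n_population, n_connected,
                                        n_excitatory, weight_range,
                                        seed = s(1))
    base <- generate_raster(spec, n_trials, trial_duration, seed = s(2))
    test <- generate_raster(spec, n_test_trials, trial_duration,
                            seed = s(4))
    test <- apply_stimulation(test, test_protocol, seed = s(5))$raster
    y_test <- threshold_forward(test, w_true, threshold)
    for (ki in seq_len(nk)) {
      k <- stimulus_counts[ki]
      raster <- if (k == 0) base else
        apply_stimulation(base,
                          stimulation_protocol(k, n_stimulated_cells,
                                               stim_rate, stim_duration),
                          seed = s(3))$raster
      y <- threshold_forward(raster, w_true, threshold)
      fit <- perceptron_fit(raster, y, model = "threshold", lr = lr,
                            iterations = iterations, actual = w_true,
                            threshold = threshold)
      ev <- evaluate_run(coef(fit), w_true, y_test, predict(fit, test),
                         scheme)
      rmse[r, ki] <- ev$rmse_weights
      pearson[r, ki] <- ev$pearson_r
      tpr[r, ki] <- ev$tpr
      ppv[r, ki] <- ev$ppv
      pcr[r, ki, ] <- ev$per_class_rmse
      pca[r, ki, ] <- ev$per_class_accuracy
    }
  }
  by_count <- data.frame(
    k = stimulus_counts,
    rmse = colMeans(rmse), rmse_se = apply(rmse, 2, std_err),
    pearson_r = colMeans(pearson),
    tpr = colMeans(tpr), tpr_se = apply(tpr, 2, std_err),
    ppv = colMeans(ppv), ppv_se = apply(ppv, 2, std_err))
  lv <- scheme$levels
  structure(list(counts = stimulus_counts, by_count = by_count,
                 rmse = rmse,
                 per_class_rmse = matrix(colMeans(pcr, dims = 1)[seq_len(nk), ],
                                         nk, 5, dimnames = list(NULL, lv)),
                 per_class_accuracy = matrix(colMeans(pca, dims = 1)[seq_len(nk), ],
                                             nk, 5,
                                             dimnames = list(NULL, lv))),
            class = "stimulus_sweep")
}

#' @export
print.stimulus_sweep <- function(x, ...) {
  cat("Stimulus-number sweep\n")
  print(round(x$by_count, 4))
  invisible(x)
}

#' Train on recurrent circuits driven by multichannel recordings
#'
#' For each dataset, builds a recurrent circuit, synthesizes (or accepts) a
#' multichannel recording, maps its channels onto each postsynaptic
#' neuron's presynaptic slots by tiling, simulates the actual postsynaptic
#' spikes with the true in-edge weights through the LIF model, and derives
#' the weights with [perceptron_fit()]. Each dataset is run twice on
#' matched surrogates: with the elevated-rate stimulation epoch
#' (`stim_gain`) and without it (gain 1), and weight errors are summarized
#' per subpopulation from [cluster_subpopulations()] of the true weights.
#'
#' @param n_datasets number of recording datasets (default 6).
#' @param master_seed integer master seed.
#' @param n_neurons,in_degree,p_uni,p_rec,rec_strength_factor,ei_ratio
#'   circuit construction, see [build_recurrent_circuit()].
#' @param n_channels,total_duration,stim_epoch_duration,stim_gain
#'   surrogate recording, see [generate_surrogate_recording()].
#' @param input_rasters optional list of `n_datasets` single-trial rasters
#'   standing in for the surrogate recordings (the "stimulated" input);
#'   matched unstimulated surrogates are still generated.
#' @param n_post postsynaptic circuit neurons trained per dataset
#'   (default 1).
#' @param lr,iterations perceptron training (defaults 0.01, 100).
#' @param lif a [lif_params()].
#' @param n_groups subpopulation groups per sign (default 3).
#' @return An object of class `"circuit_experiment"`: list with
#'   `per_dataset` (data frame of overall RMSE with and without the
#'   stimulation epoch), `subpop_rmse` (dataset x subpopulation matrices
#'   `stimulated` and `unstimulated`) and `delta_w` (per-dataset list of
#'   derived-minus-actual weights by subpopulation).
#' @export
run_circuit_experiment <- function(n_datasets = 6, master_seed = 1,
                                   n_neurons = 400, in_degree = 120,
                                   p_uni = 0.13, p_rec = 0.06,
                                   rec_strength_factor = 1.5, ei_ratio = 4,
                                   n_channels = 64, total_duration = 900,
                                   stim_epoch_duration = 60, stim_gain = 3,
                                   input_rasters = NULL, n_post = 1,
                                   lr = 0.01, iterations = 100,
                                   lif = lif_params(), n_groups = 3) {
  if (!is.null(input_rasters) && length(input_rasters) != n_datasets)
    stop_field("input_rasters", "need one raster per dataset")
  subpops <- as.vector(outer(c("weak", "mid", "strong"),
                             c("excitatory", "inhibitory"), paste))
  per_dataset <- data.frame(dataset = seq_len(n_datasets),
                            rmse_stimulated = NA_real_,
                            rmse_unstimulated = NA_real_)
  sub_stim <- sub_unstim <- matrix(NA_real_, n_datasets, length(subpops),
                                   dimnames = list(NULL, subpops))
  delta_w <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    s <- function(stage) child_seed(master_seed, d, stage)
    graph <- build_recurrent_circuit(n_neurons, in_degree, p_uni, p_rec,
                                     rec_strength_factor, ei_ratio,
                                     seed = s(1))
    rec_stim <- if (!is.null(input_rasters)) input_rasters[[d]] else
      generate_surrogate_recording(n_channels, total_duration,
                                   stim_epoch_duration,
                                   stim_gain = stim_gain, seed = s(2))
    # matched no-stimulation surrogate: same seed, gain 1 (same baseline
    # rates, independent spike placement)
    rec_unstim <- generate_surrogate_recording(
      n_channels, total_duration, stim_epoch_duration,
      baseline_rates = rec_stim$meta$baseline_rates %||% NULL,
      stim_gain = 1, seed = s(3))
    posts <- seq_len(n_post)
    dws <- list()
    rs <- ru <- ssub <- usub <- NULL
    for (j in posts) {
      w_true <- circuit_in_edges(graph, j)$weight
      groups <- cluster_subpopulations(w_true, n_groups)
      fit_s <- fit_circuit_post(rec_stim, w_true, lr, iterations, lif)
      fit_u <- fit_circuit_post(rec_unstim, w_true, lr, iterations, lif)
      rs <- c(rs, weight_rmse(coef(fit_s), w_true))
      ru <- c(ru, weight_rmse(coef(fit_u), w_true))
      ssub <- rbind(ssub, vapply(subpops, function(g) {
        sel <- which(groups == g)
        if (!length(sel)) NA_real_ else
          weight_rmse(coef(fit_s), w_true, sel)
      }, 1))
      usub <- rbind(usub, vapply(subpops, function(g) {
        sel <- which(groups == g)
        if (!length(sel)) NA_real_ else
          weight_rmse(coef(fit_u), w_true, sel)
      }, 1))
      dws[[j]] <- data.frame(subpop = groups,
                             delta_w = coef(fit_s) - w_true)
    }
    per_dataset$rmse_stimulated[d] <- mean(rs)
    per_dataset$rmse_unstimulated[d] <- mean(ru)
    sub_stim[d, ] <- colMeans(ssub)
    sub_unstim[d, ] <- colMeans(usub)
    delta_w[[d]] <- do.call(rbind, dws)
  }
  structure(list(per_dataset = per_dataset,
                 subpop_rmse = list(stimulated = sub_stim,
                                    unstimulated = sub_unstim),
                 delta_w = delta_w),
            class = "circuit_experiment")
}

# Tile recording channels onto the in_degree presynaptic slots of one
# postsynaptic neuron and fit its weights through the LIF model.
fit_circuit_post <- function(recording, w_true, lr, iterations, lif) {
  slots <- tile_channels(recording, length(w_true))
  y <- lif_forward(slots, w_true, lif)
  perceptron_fit(slots, y, model = "lif", lr = lr,
                 iterations = iterations, actual = w_true, lif = lif)
}

# Map an n-channel recording onto n_slots presynaptic inputs by tiling
# (channel c drives every slot congruent to c).
tile_channels <- function(recording, n_slots) {
  stopifnot(inherits(recording, "spike_raster"))
  nc <- recording$n_neurons
  reps <- ceiling(n_slots / nc)
  ev <- recording$events
  out <- do.call(rbind, lapply(seq_len(reps), function(t) {
    slot <- ev$neuron + (t - 1L) * nc
    keep <- slot <= n_slots
    data.frame(neuron = slot[keep], trial = ev$trial[keep],
               bin = ev$bin[keep])
  }))
  spike_raster(out, n_slots, recording$n_trials,
               recording$trial_duration, recording$dt,
               meta = recording$meta, validate = FALSE)
}

#' @export
print.circuit_experiment <- function(x, ...) {
  cat(sprintf("Circuit experiment, %d datasets\n", nrow(x$per_dataset)))
  cat(sprintf("  weight RMSE with stimulation epoch: %.3f +/- %.3f mV\n",
              mean(x$per_dataset$rmse_stimulated),
              std_err(x$per_dataset$rmse_stimulated)))
  cat(sprintf("  without:                            %.3f +/- %.3f mV\n",
              mean(x$per_dataset$rmse_unstimulated),
              std_err(x$per_dataset$rmse_unstimulated)))
  invisible(x)
}
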