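# Small-scale experiment configurations keep the suite fast; the full-size
# protocols live in the acceptance checks.
tiny_ff <- function(condition, counts = NULL, reps = 2, seed = 42) {
  args <- list(n_replicates = reps, master_seed = seed, n_population = 60,
               n_connected = 30, n_excitatory = 24, n_trials = 100,
               trial_duration = 500, n_stimulations = 4,
               n_stimulated_cells = 15, lr = 0.02, iterations = 15,
               threshold = 10, n_test_trials = 100)
  if (is.null(counts)) {
    do.call(run_feedforward_experiment, c(list(condition = condition), args))
  } else {
    args$n_stimulations <- NULL
    do.call(run_stimulus_sweep, c(list(stimulus_counts = counts), args))
  }
}

test_that("feedforward experiments are reproducible and well-formed", {
  a <- tiny_ff("silent_stimulated")
  b <- tiny_ff("silent_stimulated")
  expect_identical(a$replicates, b$replicates)
  expect_identical(nrow(a$replicates), 2L)
  expect_true(all(c("rmse", "pearson_r", "tpr", "ppv", "performance")
                  %in% names(a$replicates)))
  # SE is sample SD over sqrt(n), verified against direct computation
  expect_equal(a$aggregate["se", "rmse"],
               sd(a$replicates$rmse) / sqrt(2))
  expect_equal(a$aggregate["mean", "tpr"], mean(a$replicates$tpr))
  # kept runs expose the weight vectors for downstream calibration
  expect_length(a$runs, 2)
  expect_length(a$runs[[1]]$derived, 60)
  expect_identical(sum(a$runs[[1]]$actual != 0), 30L)
})

test_that("hyperactive recovery beats the silent condition at any scale", {
  hy <- tiny_ff("hyperactive")
  si <- tiny_ff("silent_unstimulated")
  expect_lt(hy$aggregate["mean", "rmse"], si$aggregate["mean", "rmse"])
  expect_gt(hy$aggregate["mean", "pearson_r"],
            si$aggregate["mean", "pearson_r"])
})

test_that("skipping test trials drops only the prediction scores", {
  ex <- run_feedforward_experiment("hyperactive", n_replicates = 1,
                                   master_seed = 3, n_population = 40,
                                   n_connected = 20, n_excitatory = 16,
                                   n_trials = 40, trial_duration = 500,
                                   iterations = 10, n_test_trials = 0)
  expect_true(is.na(ex$replicates$tpr))
  expect_false(is.na(ex$replicates$rmse))
})

test_that("the stimulus sweep shares seeds so count 0 equals no stimulation", {
  sw <- tiny_ff(NULL, counts = c(0, 4))
  ex <- tiny_ff("silent_unstimulated")
  expect_equal(sw$rmse[, 1], ex$replicates$rmse)
  expect_identical(dim(sw$rmse), c(2L, 2L))
  expect_identical(sw$by_count$k, c(0, 4))
  expect_true(all(is.finite(sw$by_count$rmse)))
  # stimulation does not hurt weight recovery in the paired design
  expect_lte(sw$by_count$rmse[2], sw$by_count$rmse[1])
})

test_that("single-silent-neuron perturbation drives only its target", {
  ex <- run_feedforward_experiment("single_silent_perturbation",
                                   n_replicates = 1, master_seed = 9,
                                   n_population = 40, n_connected = 20,
                                   n_excitatory = 16, n_trials = 30,
                                   trial_duration = 500, iterations = 10,
                                   n_stimulations = 2, threshold = 10,
                                   n_test_trials = 0)
  expect_false(is.na(ex$replicates$rmse))
  expect_true(is.finite(ex$replicates$pearson_r))
})

test_that("circuit experiment recovers in-edge weights from recordings", {
  ce <- run_circuit_experiment(n_datasets = 1, master_seed = 2,
                               n_neurons = 50, in_degree = 20,
                               n_channels = 8, total_duration = 60,
                               stim_epoch_duration = 10, stim_gain = 4,
                               iterations = 40)
  expect_identical(nrow(ce$per_dataset), 1L)
  expect_true(is.finite(ce$per_dataset$rmse_stimulated))
  expect_true(is.finite(ce$per_dataset$rmse_unstimulated))
  expect_identical(dim(ce$subpop_rmse$stimulated), c(1L, 6L))
  expect_identical(nrow(ce$delta_w[[1]]), 20L)
  # rerunning with the same master seed is bit-identical
  ce2 <- run_circuit_experiment(n_datasets = 1, master_seed = 2,
                                n_neurons = 50, in_degree = 20,
                                n_channels = 8, total_duration = 60,
                                stim_epoch_duration = 10, stim_gain = 4,
                                iterations = 40)
  expect_identical(ce$per_dataset, ce2$per_dataset)
  expect_identical(ce$delta_w, ce2$delta_w)
})
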