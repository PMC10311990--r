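test_that("weight RMSE matches hand computation and honours subsets", {
  expect_identical(weight_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(weight_rmse(c(1, 1), c(0, 0)), 1)
  expect_equal(weight_rmse(c(1, 5), c(0, 5), subset = 1), 1)
  expect_error(weight_rmse(1:3, 1:2), "equal length")
  expect_error(weight_rmse(1:3, 2:4, subset = integer()), "subset")
})

test_that("spike scores equal confusion-matrix sensitivity and precision", {
  s <- spike_prediction_scores(c(1, 1, 0, 1, 1, 0), c(1, 1, 0, 1, 1, 0))
  expect_equal(unlist(s), c(tpr = 1, ppv = 1, performance = 1))

  # 4 actual spikes, 3 predicted correctly plus 1 extra
  s <- spike_prediction_scores(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 0))
  expect_equal(s$tpr, 0.75)
  expect_equal(s$ppv, 0.75)
  expect_equal(s$performance, 0.75)

  # exhaustive check over all length-6 binary pairs with nonempty sets
  grids <- expand.grid(replicate(6, 0:1, simplify = FALSE))
  pats <- as.matrix(grids)
  for (i in seq_len(64)) for (j in seq_len(64)) {
    a <- pats[i, ]; p <- pats[j, ]
    if (sum(a) == 0 || sum(p) == 0) next
    tp <- sum(a == 1 & p == 1)
    s <- spike_prediction_scores(a, p)
    expect_equal(s$tpr, tp / sum(a))
    expect_equal(s$ppv, tp / sum(p))
    expect_equal(s$performance, (s$tpr + s$ppv) / 2)
  }

  # empty reference sets are undefined, not coerced to 1
  expect_warning(s <- spike_prediction_scores(c(0, 0), c(1, 0)), "TPR")
  expect_true(is.na(s$tpr))
  expect_warning(s <- spike_prediction_scores(c(1, 0), c(0, 0)), "PPV")
  expect_true(is.na(s$ppv))
  expect_error(spike_prediction_scores(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("weight classification partitions [-8, 8] with boundaries toward zero", {
  expect_identical(as.character(classify_weights(c(5, 0, -6, 1, -1))),
                   c("strong excitatory", "unconnected",
                     "strong inhibitory", "weak excitatory",
                     "weak inhibitory"))
  eps <- 0.16
  expect_identical(as.character(classify_weights(c(eps, -eps, 4, -4, 8, -8))),
                   c("unconnected", "unconnected", "weak excitatory",
                     "weak inhibitory", "strong excitatory",
                     "strong inhibitory"))
  expect_error(classify_weights(8.5), "range")

  # totality and interval agreement on a fine grid (independent oracle)
  w <- seq(-8, 8, by = 1e-3)
  got <- classify_weights(w)
  expect_false(anyNA(got))
  oracle <- ifelse(w < -4, "strong inhibitory",
            ifelse(w < -eps, "weak inhibitory",
            ifelse(w <= eps, "unconnected",
            ifelse(w <= 4, "weak excitatory", "strong excitatory"))))
  expect_identical(as.character(got), oracle)
})

test_that("per-class accuracy matches direct counting", {
  scheme <- classification_scheme()
  actual <- c(-6, -2, 0, 1, 5, 7)
  expect_equal(unname(classification_accuracy(actual, actual, scheme)),
               rep(1, 5))
  # two deliberate misassignments: -6 -> weak inhibitory, 1 -> unconnected
  derived <- c(-3, -2, 0, 0.1, 5, 7)
  acc <- classification_accuracy(derived, actual, scheme)
  expect_equal(unname(acc["strong inhibitory"]), 0)
  expect_equal(unname(acc["weak inhibitory"]), 1)
  expect_equal(unname(acc["weak excitatory"]), 0)
  expect_equal(unname(acc["strong excitatory"]), 1)
  expect_equal(unname(acc["unconnected"]), 1)
  # an unpopulated class is undefined
  acc2 <- classification_accuracy(c(1, 2), c(1, 2), scheme)
  expect_true(is.na(acc2["strong inhibitory"]))
})

test_that("epsilon calibration pools unconnected errors over good runs", {
  runs <- list(
    list(derived = c(0, 0, 5), actual = c(0, 0, 5), performance = 0.995),
    list(derived = c(0.1, -0.1, 4), actual = c(0, 0, 4),
         performance = 0.992),
    list(derived = c(3, 3, 3), actual = c(0, 0, 3), performance = 0.5))
  # only the first two qualify; pooled RMSE over their unconnected cells
  expect_equal(calibrate_epsilon(runs), sqrt(mean(c(0, 0, 0.01, 0.01))))
  expect_equal(calibrate_epsilon(runs[2]), 0.1)
  expect_identical(calibrate_epsilon(runs[1]), 0)
  expect_error(calibrate_epsilon(runs[3]), "performance")
  expect_error(calibrate_epsilon(list(list(derived = 1, actual = 1,
                                           performance = 1))),
               "unconnected")
})

test_that("subpopulation clustering separates magnitudes within each sign", {
  w <- c(1, 1.1, 4, 4.1, 7, 7.1)
  lab <- cluster_subpopulations(w)
  expect_identical(lab, c("weak excitatory", "weak excitatory",
                          "mid excitatory", "mid excitatory",
                          "strong excitatory", "strong excitatory"))
  # signs never share a group; zeros are unconnected
  w2 <- c(-1, -4.5, -7, 2, 5, 8, 0)
  lab2 <- cluster_subpopulations(w2)
  expect_identical(lab2[1:3], c("weak inhibitory", "mid inhibitory",
                                "strong inhibitory"))
  expect_identical(lab2[4:6], c("weak excitatory", "mid excitatory",
                                "strong excitatory"))
  expect_true(is.na(lab2[7]))
  expect_error(cluster_subpopulations(rep(2, 5)), "separation")
})

test_that("evaluate_run bundles the per-run report", {
  actual <- c(-6, -2, 0, 1, 5, 0)
  derived <- actual + c(0.1, -0.1, 0, 0.05, -0.2, 0.02)
  ev <- evaluate_run(derived, actual, actual_spikes = c(1, 0, 1, 0),
                     predicted_spikes = c(1, 0, 1, 0))
  expect_equal(ev$rmse_weights, weight_rmse(derived, actual))
  expect_equal(ev$performance, 1)
  expect_equal(unname(ev$per_class_accuracy["strong inhibitory"]), 1)
  expect_equal(unname(ev$per_class_rmse["unconnected"]),
               sqrt(mean(c(0, 0.02^2))))
})
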