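test_that("the elementary update follows lr * (y - y') * x exactly", {
  expect_equal(perceptron_update(c(0.5, -0.2), c(1, 1), 1, 1, 0.01),
               c(0.5, -0.2))
  expect_equal(perceptron_update(c(0, 0), c(1, 0), 1, 0, 0.01),
               c(0.01, 0))
  expect_equal(perceptron_update(c(0.3, 0.3), c(1, 0), 0, 1, 0.05),
               c(0.25, 0.3))
  expect_error(perceptron_update(c(0, 0), c(1, 0, 1), 1, 0, 0.01), "length")
})

test_that("inputs that never spike keep their initial weight exactly", {
  mat <- rbind(c(1, 0, 1, 1), c(0, 1, 1, 0), c(0, 0, 0, 0))
  r <- raster_from_matrix(mat)
  y <- c(1L, 0L, 1L, 0L)
  fit <- perceptron_fit(r, y, lr = 0.3, iterations = 50)
  expect_identical(coef(fit)[3], 0)
  fit2 <- perceptron_fit(r, y, lr = 0.3, iterations = 50,
                         init = "uniform_small", seed = 1)
  w0 <- with(list(), {set.seed(1); runif(3, -0.01, 0.01)})
  expect_identical(coef(fit2)[3], w0[3])
})

test_that("first-pass updates scale linearly with the learning rate", {
  # with an unreachable threshold every prediction stays 0, so the first
  # pass accumulates lr * sum_y(x) exactly
  set.seed(2)
  mat <- matrix(rbinom(5 * 40, 1, 0.3), 5, 40)
  y <- rbinom(40, 1, 0.4)
  r <- raster_from_matrix(mat)
  f1 <- perceptron_fit(r, y, lr = 0.01, iterations = 1, threshold = 1e6)
  f3 <- perceptron_fit(r, y, lr = 0.03, iterations = 1, threshold = 1e6)
  expect_equal(coef(f3), 3 * coef(f1))
  expect_equal(coef(f1), 0.01 * as.numeric(mat %*% y))
})

test_that("a separable toy problem is learned to zero training error", {
  patterns <- t(expand.grid(0:1, 0:1, 0:1))  # all 8 binary inputs
  prob <- pattern_problem(patterns, w_true = c(15, 15, 25), threshold = 20,
                          times = 25)
  fit <- perceptron_fit(prob$raster, prob$y, lr = 0.5, iterations = 100)
  expect_identical(fit$trace$error_rate[fit$iterations], 0)
  expect_identical(predict(fit, prob$raster), prob$y)
})

test_that("hyperactive populations are recovered at small scale", {
  fx <- hyper_fixture(n = 60, n_conn = 30, n_exc = 24, trials = 150,
                      dur = 1000, seed = 5)
  fit <- perceptron_fit(fx$raster, fx$y, lr = 0.01, iterations = 25,
                        actual = fx$w, threshold = fx$threshold)
  rmse <- fit$trace$rmse
  expect_lt(rmse[25], 0.8)
  expect_lt(rmse[25], rmse[1])
  expect_gt(cor(coef(fit), fx$w), 0.98)
  # residuals and summary expose the comparison
  expect_equal(residuals(fit), coef(fit) - fx$w)
  s <- summary(fit)
  expect_equal(s$rmse, weight_rmse(coef(fit), fx$w))
})

test_that("training through the LIF forward model recovers weights", {
  w <- build_feedforward_weights(30, 15, 12, seed = 6)
  r <- generate_raster(population_spec(30, silent_fraction = 0), 200, 1000,
                       seed = 7)
  p <- lif_params(V_t = -25)
  y <- lif_forward(r, w, p)
  fit <- perceptron_fit(r, y, model = "lif", lr = 0.01, iterations = 50,
                        actual = w, lif = p)
  expect_lt(fit$trace$rmse[50], 1.3)
  expect_gt(cor(coef(fit), w), 0.98)
  # zero-weight ground truth stays exactly at zero initialization
  y0 <- lif_forward(r, rep(0, 30))
  fit0 <- perceptron_fit(r, y0, model = "lif", iterations = 10)
  expect_identical(coef(fit0), rep(0, 30))
})

test_that("the learning-rate scan returns the minimizing candidate", {
  fx <- hyper_fixture(n = 40, n_conn = 20, n_exc = 16, trials = 100,
                      dur = 1000, seed = 8)
  # single candidate is best by construction
  one <- optimize_learning_rate(fx$raster, fx$y, candidate_rates = 0.005,
                                iterations = 5, actual = fx$w,
                                threshold = fx$threshold)
  expect_identical(one$best_rate, 0.005)
  expect_error(optimize_learning_rate(fx$raster, fx$y,
                                      candidate_rates = numeric()),
               "candidate_rates")

  scan <- optimize_learning_rate(fx$raster, fx$y,
                                 candidate_rates = 10^seq(-5, -2, 1),
                                 iterations = 20, actual = fx$w,
                                 threshold = fx$threshold)
  expect_identical(nrow(scan$curve), 4L)
  expect_true(all(is.finite(scan$curve$rmse)))
  expect_identical(scan$curve$rmse[scan$curve$lr == scan$best_rate],
                   min(scan$curve$rmse))
  # at few iterations, tiny rates underfit relative to the optimum
  expect_lt(min(scan$curve$rmse), scan$curve$rmse[1])

  # duplicated candidates give identical entries; ties break small
  dup <- optimize_learning_rate(fx$raster, fx$y,
                                candidate_rates = c(0.01, 0.01),
                                iterations = 5, actual = fx$w,
                                threshold = fx$threshold)
  expect_identical(dup$curve$rmse[1], dup$curve$rmse[2])
  expect_identical(dup$best_rate, 0.01)
})
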