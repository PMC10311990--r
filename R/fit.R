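#' One perceptron weight update
#'
#' The elementary learning step: `w_i <- w_i + lr * (y - y_pred) * x_i`.
#' Inputs that were silent in the bin (`x_i = 0`) are never touched, and a
#' correct prediction (`y == y_pred`) leaves all weights unchanged.
#'
#' @param weights current weight vector.
#' @param x per-input bin values (0/1).
#' @param y actual postsynaptic output bit.
#' @param y_pred predicted output bit.
#' @param lr learning rate (> 0).
#' @return Updated weight vector.
#' @export
#' @examples
#' perceptron_update(c(0, 0), x = c(1, 0), y = 1, y_pred = 0, lr = 0.01)
perceptron_update <- function(weights, x, y, y_pred, lr) {
  if (length(x) != length(weights))
    stop("length(x) must equal length(weights)")
  stopifnot(y %in% c(0, 1), y_pred %in% c(0, 1), lr > 0)
  weights + lr * (y - y_pred) * x
}

#' Derive connection weights with the online perceptron rule
#'
#' Fits per-input synaptic weights from a presynaptic raster and the
#' postsynaptic spike train it should explain. Each training pass visits
#' every bin of every trial in chronological order: the forward model
#' (memoryless threshold unit or leaky integrate-and-fire) predicts the
#' postsynaptic bit from the current weights, then every input that spiked
#' in the bin is nudged by `lr * (y - y_pred)`. The pass is repeated
#' `iterations` times. For the LIF model the membrane state carries across
#' bins within a trial and resets to rest at trial boundaries.
#'
#' @param raster presynaptic [spike_raster()].
#' @param post postsynaptic spike train: binary vector in trial-major bin
#'   order, or a single-neuron [spike_raster()] with matching dimensions.
#' @param model `"threshold"` (default) or `"lif"`.
#' @param lr learning rate (default 0.01, the optimized value for the
#'   default protocol; see [optimize_learning_rate()]).
#' @param iterations training passes over the data (default 100).
#' @param init `"zeros"` (default; makes the silent-input invariance exact
#'   and runs reproducible without a seed) or `"uniform_small"`.
#' @param init_range half-width of the uniform initialization when
#'   `init = "uniform_small"`.
#' @param actual optional ground-truth weight vector; when supplied the
#'   per-iteration trace records the RMSE of the derived weights against it.
#' @param threshold threshold-unit spike threshold in mV (default 20).
#' @param lif a [lif_params()] used when `model = "lif"`.
#' @param seed RNG seed (only consumed by random initialization).
#' @return An object of class `"perceptron_fit"` with components
#'   `coefficients` (derived weights), `trace` (data frame `iteration`,
#'   `error_rate`, `rmse`), `model`, `lr`, `iterations` and the training
#'   dimensions. Methods: [coef()], `print`, `summary`, [predict()] on new
#'   rasters, `plot`, `residuals`.
#' @export
#' @examples
#' w <- build_feedforward_weights(40, 20, 16, seed = 1)
#' r <- generate_raster(population_spec(40, silent_fraction = 0), 20, 500,
#'                      seed = 2)
#' fit <- perceptron_fit(r, threshold_forward(r, w), iterations = 25,
#'                       actual = w)
#' fit
perceptron_fit <- function(raster, post,
                           model = c("threshold", "lif"),
                           lr = 0.01, iterations = 100,
                           init = c("zeros", "uniform_small"),
                           init_range = 0.01, actual = NULL,
                           threshold = 20, lif = lif_params(),
                           seed = NULL) {
  model <- match.arg(model)
  init <- match.arg(init)
  stopifnot(inherits(raster, "spike_raster"))
  if (lr <= 0) stop_field("lr", "must be > 0")
  if (iterations < 1) stop_field("iterations", "must be >= 1")
  n_bins_total <- raster$n_trials * raster$n_bins
  y <- as_spike_train(post, n_bins_total)
  if (!is.null(actual) && length(actual) != raster$n_neurons)
    stop("length(actual) must equal the raster's neuron count")
  w0 <- if (init == "zeros") numeric(raster$n_neurons) else
    with_seed(seed, runif(raster$n_neurons, -init_range, init_range))
  csr <- raster_csr(raster)
  res <- perceptron_train_cpp(csr$ptr, csr$idx, y, w0, lr,
                              as.integer(iterations),
                              if (model == "threshold") 0L else 1L,
                              threshold, raster$n_bins, lif$V_e, lif$R_m,
                              lif$tau_m, raster$dt, lif$I_post, lif$V_t,
                              lif$V_reset,
                              if (is.null(actual)) NULL else
                                as.numeric(actual))
  structure(list(coefficients = res$weights,
                 trace = data.frame(iteration = seq_len(iterations),
                                    error_rate = res$error_rate,
                                    rmse = res$rmse),
                 model = model, lr = lr, iterations = as.integer(iterations),
                 init = init, actual = actual, threshold = threshold,
                 lif = lif, n_neurons = raster$n_neurons,
                 n_trials = raster$n_trials,
                 trial_duration = raster$trial_duration, dt = raster$dt,
                 call = match.call()),
            class = "perceptron_fit")
}

#' @export
coef.perceptron_fit <- function(object, ...) object$coefficients

#' @export
print.perceptron_fit <- function(x, ...) {
  cat(sprintf("Perceptron-derived weights (%s model): %d inputs, lr = %g, %d iterations\n",
              x$model, x$n_neurons, x$lr, x$iterations))
  cat(sprintf("  final training error rate: %.4g per bin\n",
              x$trace$error_rate[x$iterations]))
  if (!is.null(x$actual))
    cat(sprintf("  weight RMSE vs actual: %.4g mV (r = %.3f)\n",
                x$trace$rmse[x$iterations],
                cor(x$coefficients, x$actual)))
  invisible(x)
}

#' @export
summary.perceptron_fit <- function(object, ...) {
  cls <- classify_weights(pmin(pmax(object$coefficients, -8), 8))
  out <- list(fit = object, class_counts = table(cls),
              weight_summary = summary(object$coefficients))
  if (!is.null(object$actual)) {
    out$rmse <- weight_rmse(object$coefficients, object$actual)
    out$pearson_r <- cor(object$coefficients, object$actual)
  }
  class(out) <- "summary.perceptron_fit"
  out
}

#' @export
print.summary.perceptron_fit <- function(x, ...) {
  print(x$fit)
  cat("Derived weights (mV):\n")
  print(x$weight_summary)
  cat("Derived connection classes:\n")
  print(x$class_counts)
  if (!is.null(x$rmse))
    cat(sprintf("RMSE vs actual: %.4g mV; Pearson r = %.4f\n",
                x$rmse, x$pearson_r))
  invisible(x)
}

#' Predict postsynaptic spikes from a fitted model
#'
#' Runs the fit's forward model with the derived weights over a new
#' presynaptic raster.
#'
#' @param object a [perceptron_fit()].
#' @param raster a [spike_raster()] with the same neuron count.
#' @param ... unused.
#' @return Integer 0/1 spike train in trial-major bin order.
#' @export
predict.perceptron_fit <- function(object, raster, ...) {
  stopifnot(inherits(raster, "spike_raster"))
  if (object$model == "threshold")
    threshold_forward(raster, object$coefficients, object$threshold)
  else
    lif_forward(raster, object$coefficients, object$lif)
}

#' @export
residuals.perceptron_fit <- function(object, ...) {
  if (is.null(object$actual))
    stop("residuals require ground-truth weights ('actual')")
  object$coefficients - object$actual
}

#' @export
plot.perceptron_fit <- function(x, which = c("weights", "trace"), ...) {
  which <- match.arg(which)
  if (which == "weights" && !is.null(x$actual)) {
    plot(x$actual, x$coefficients, xlab = "actual weight (mV)",
         ylab = "derived weight (mV)",
         main = sprintf("Derived vs actual weights (r = %.3f)",
                        cor(x$coefficients, x$actual)), ...)
    abline(0, 1, lty = 2)
  } else {
    tr <- x$trace
    metric <- if (all(is.na(tr$rmse))) tr$error_rate else tr$rmse
    lab <- if (all(is.na(tr$rmse))) "training error rate" else
      "weight RMSE (mV)"
    plot(tr$iteration, metric, type = "l", xlab = "iteration",
         ylab = lab, main = "Training trace", ...)
  }
  invisible(x)
}

#' Scan learning rates and pick the best
#'
#' Trains one model per candidate rate and returns the rate minimizing the
#' final weight RMSE against ground truth (when `actual` is supplied) or
#' the final training error rate otherwise, together with the full curve.
#' Ties break toward the smaller rate.
#'
#' @inheritParams perceptron_fit
#' @param candidate_rates learning rates to evaluate (>= 2 values unless a
#'   single candidate is intended; must be non-empty).
#' @return List with `best_rate`, `curve` (data frame `lr`, `rmse`,
#'   `error_rate`) and `fits` (the per-candidate [perceptron_fit()]s).
#' @export
optimize_learning_rate <- function(raster, post,
                                   candidate_rates = 10^seq(-5, -2,
                                                            length.out = 7),
                                   iterations = 100, actual = NULL,
                                   model = c("threshold", "lif"),
                                   threshold = 20, lif = lif_params(),
                                   seed = NULL) {
  model <- match.arg(model)
  if (length(candidate_rates) == 0)
    stop_field("candidate_rates", "must be non-empty")
  fits <- lapply(candidate_rates, function(lr)
    perceptron_fit(raster, post, model = model, lr = lr,
                   iterations = iterations, actual = actual,
                   threshold = threshold, lif = lif, seed = seed))
  final <- function(f, col) f$trace[[col]][f$iterations]
  curve <- data.frame(lr = candidate_rates,
                      rmse = vapply(fits, final, 1, col = "rmse"),
                      error_rate = vapply(fits, final, 1,
                                          col = "error_rate"))
  score <- if (is.null(actual)) curve$error_rate else curve$rmse
  ord <- order(score, candidate_rates)  # ties toward the smaller rate
  list(best_rate = candidate_rates[ord[1]], curve = curve, fits = fits)
}
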