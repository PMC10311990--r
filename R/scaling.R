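#' Expected stimulation coverage of a population
#'
#' Coverage after k epochs is the fraction of the population driven in at
#' least one epoch. With m cells resampled uniformly per epoch out of N,
#' the closed form is `1 - (1 - m/N)^k`; Monte-Carlo mode simulates the
#' resampling and reports the mean empirical coverage, agreeing with the
#' closed form within sampling error.
#'
#' @param n_population population size N.
#' @param n_per_epoch cells driven per epoch m (default 50); must not
#'   exceed N.
#' @param max_epochs largest epoch count k evaluated.
#' @param mode `"analytic"` (default) or `"monte_carlo"`.
#' @param n_rep Monte-Carlo repetitions (default 200).
#' @param seed RNG seed (Monte-Carlo only).
#' @return Data frame with columns `k` (1..max_epochs) and `coverage`.
#' @export
#' @examples
#' coverage_curve(200, 50, 5)
coverage_curve <- function(n_population, n_per_epoch = 50, max_epochs,
                           mode = c("analytic", "monte_carlo"),
                           n_rep = 200, seed = NULL) {
  mode <- match.arg(mode)
  if (n_per_epoch > n_population)
    stop_field("n_per_epoch", "must not exceed n_population")
  k <- seq_len(max_epochs)
  if (mode == "analytic") {
    cov <- 1 - (1 - n_per_epoch / n_population)^k
  } else {
    cov <- with_seed(seed, {
      acc <- numeric(max_epochs)
      for (r in seq_len(n_rep)) {
        hit <- logical(n_population)
        for (i in k) {
          hit[sample.int(n_population, n_per_epoch)] <- TRUE
          acc[i] <- acc[i] + mean(hit)
        }
      }
      acc / n_rep
    })
  }
  data.frame(k = k, coverage = cov)
}

#' Mean population spike rate as a function of stimulus number
#'
#' For each stimulus count the stimulated raster is generated and the mean
#' population rate computed as total spikes / (neurons x averaging window).
#' With epochs in disjoint windows the rate grows linearly in the stimulus
#' count, with slope proportional to the stimulated fraction m/N (hence
#' decreasing in N).
#'
#' @param spec a [population_spec()].
#' @param stimulus_counts integer vector of epoch counts to evaluate.
#' @param n_trials,trial_duration raster dimensions (ms).
#' @param protocol_args list of arguments passed to
#'   [stimulation_protocol()] besides the count.
#' @param averaging_window window in seconds dividing the spike count;
#'   default `NULL` uses the full training duration
#'   (`n_trials * trial_duration`).
#' @param seed RNG seed; the baseline raster is shared across counts.
#' @return Data frame with columns `k` and `rate` (Hz).
#' @export
rate_curve <- function(spec, stimulus_counts, n_trials, trial_duration,
                       protocol_args = list(), averaging_window = NULL,
                       seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(averaging_window) && averaging_window <= 0)
    stop_field("averaging_window", "must be > 0")
  win <- if (is.null(averaging_window))
    n_trials * trial_duration / 1000 else averaging_window
  base <- generate_raster(spec, n_trials, trial_duration,
                          seed = child_seed(if (is.null(seed)) 0 else seed, 1))
  rate <- vapply(stimulus_counts, function(k) {
    r <- if (k == 0) base else {
      if (is.null(protocol_args$placement_mode))
        protocol_args$placement_mode <- "designated"  # k isolated epochs
      prot <- do.call(stimulation_protocol,
                      c(list(n_stimulations = k), protocol_args))
      apply_stimulation(base, prot,
                        seed = child_seed(if (is.null(seed)) 0 else seed,
                                          2, k))$raster
    }
    nrow(r$events) / (r$n_neurons * win)
  }, 1)
  data.frame(k = stimulus_counts, rate = rate)
}

#' Stimuli required to reach coverage and rate targets across sizes
#'
#' For each population size, the smallest stimulus count whose expected
#' coverage reaches `coverage_target` (closed form
#' `ceiling(log(1 - target) / log(1 - m/N))`), and optionally the smallest
#' count whose mean population rate reaches `rate_target` on a supplied
#' rate curve. Unreachable targets are reported as `NA`, not an error.
#'
#' @param sizes population sizes N.
#' @param n_per_epoch cells per epoch m (default 50).
#' @param coverage_target coverage proportion (default 0.99); a target of
#'   1 is unreachable for m < N.
#' @param rate_curves optional named list (one per size) of data frames
#'   from [rate_curve()], scanned for `rate_target`.
#' @param rate_target Hz target applied to `rate_curves`.
#' @return Data frame with `n_population`, `stimuli_to_coverage` and (when
#'   rate curves are given) `stimuli_to_rate`, plus attribute
#'   `r_squared`: the coefficient of determination of a linear fit of
#'   `stimuli_to_coverage` on N.
#' @export
#' @examples
#' stimuli_required(c(200, 1000, 2000))
stimuli_required <- function(sizes, n_per_epoch = 50,
                             coverage_target = 0.99, rate_curves = NULL,
                             rate_target = NULL) {
  if (coverage_target <= 0 || coverage_target > 1)
    stop_field("coverage_target", "must lie in (0, 1]")
  k_cov <- vapply(sizes, function(N) {
    if (n_per_epoch > N) stop_field("n_per_epoch", "exceeds a population size")
    if (n_per_epoch == N) return(1)
    if (coverage_target == 1) return(NA_real_)  # strict asymptote
    ceiling(log(1 - coverage_target) / log(1 - n_per_epoch / N))
  }, 1)
  out <- data.frame(n_population = sizes, stimuli_to_coverage = k_cov)
  if (!is.null(rate_curves) && !is.null(rate_target)) {
    out$stimuli_to_rate <- vapply(seq_along(sizes), function(i) {
      cv <- rate_curves[[i]]
      hit <- cv$k[cv$rate >= rate_target]
      if (length(hit) == 0) NA_real_ else min(hit)
    }, 1)
  }
  if (sum(!is.na(k_cov)) >= 3) {
    fit <- stats::lm(stimuli_to_coverage ~ n_population, data = out)
    attr(out, "r_squared") <- summary(fit)$r.squared
  }
  out
}
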