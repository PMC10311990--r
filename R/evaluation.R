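#' Root mean square error between derived and actual weights
#'
#' @param derived,actual weight vectors of equal length (mV).
#' @param subset optional neuron ids (1-based) to restrict the comparison
#'   to; must be non-empty.
#' @return RMSE in mV.
#' @export
#' @examples
#' weight_rmse(c(1, 1), c(0, 0))  # 1
weight_rmse <- function(derived, actual, subset = NULL) {
  if (length(derived) != length(actual))
    stop("derived and actual must have equal length")
  if (!is.null(subset)) {
    if (length(subset) == 0) stop_field("subset", "must be non-empty")
    derived <- derived[subset]
    actual <- actual[subset]
  }
  sqrt(mean((derived - actual)^2))
}

#' Sensitivity and precision of bin-wise spike prediction
#'
#' Sensitivity (TPR) is one minus the mean absolute mismatch over the bins
#' where an actual spike occurs, i.e. the fraction of actual spikes that
#' were predicted; precision (PPV) is the analogous quantity over the bins
#' where a spike was predicted. `performance` is their mean. If either
#' reference set is empty the corresponding score is undefined and reported
#' as `NA` with a warning, never coerced to 1.
#'
#' @param actual,predicted binary spike trains of equal length.
#' @return Named list with `tpr`, `ppv` and `performance`.
#' @export
#' @examples
#' spike_prediction_scores(c(1, 1, 0, 1, 1), c(1, 1, 0, 1, 0))
spike_prediction_scores <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  actual <- as_spike_train(actual)
  predicted <- as_spike_train(predicted)
  S_a <- which(actual == 1L)
  S_p <- which(predicted == 1L)
  tpr <- if (length(S_a) == 0) {
    warning("no actual spikes: TPR undefined")
    NA_real_
  } else 1 - mean(abs(actual[S_a] - predicted[S_a]))
  ppv <- if (length(S_p) == 0) {
    warning("no predicted spikes: PPV undefined")
    NA_real_
  } else 1 - mean(abs(actual[S_p] - predicted[S_p]))
  list(tpr = tpr, ppv = ppv, performance = mean(c(tpr, ppv)))
}

#' Connection-type classification scheme
#'
#' Weights are binned into five connection classes on `[-8, 8]` mV:
#' strong inhibitory `(-8, -4)`, weak inhibitory `(-4, -eps)`, unconnected
#' `(-eps, eps)`, weak excitatory `(eps, 4)` and strong excitatory
#' `(4, 8)`. The dead-zone half-width `eps` defaults to 0.16 mV, the
#' calibrated RMSE of derived weights for actually-unconnected neurons in
#' high-accuracy fits (see [calibrate_epsilon()]). Boundary values are
#' assigned to the interval on the side toward zero.
#'
#' @param epsilon dead-zone half-width in mV (default 0.16).
#' @param strong_boundary strong/weak magnitude boundary in mV (default 4).
#' @param limit weight support half-width in mV (default 8).
#' @return An object of class `"classification_scheme"`.
#' @export
classification_scheme <- function(epsilon = 0.16, strong_boundary = 4,
                                  limit = 8) {
  if (epsilon < 0 || epsilon >= strong_boundary || strong_boundary > limit)
    stop_field("epsilon", "need 0 <= epsilon < strong_boundary <= limit")
  structure(list(epsilon = epsilon, strong_boundary = strong_boundary,
                 limit = limit,
                 levels = c("strong inhibitory", "weak inhibitory",
                            "unconnected", "weak excitatory",
                            "strong excitatory")),
            class = "classification_scheme")
}

#' @export
print.classification_scheme <- function(x, ...) {
  cat(sprintf("Weight classes (mV): SI (-%g,-%g) | WI (-%g,-%g) | U (-%g,%g) | WE (%g,%g) | SE (%g,%g)\n",
              x$limit, x$strong_boundary, x$strong_boundary, x$epsilon,
              x$epsilon, x$epsilon, x$epsilon, x$strong_boundary,
              x$strong_boundary, x$limit))
  invisible(x)
}

#' Classify weights into connection types
#'
#' @param w numeric weights in `[-limit, limit]` mV.
#' @param scheme a [classification_scheme()].
#' @return Factor with the scheme's five class levels.
#' @export
#' @examples
#' classify_weights(c(-6, -1, 0, 1, 5))
classify_weights <- function(w, scheme = classification_scheme()) {
  stopifnot(inherits(scheme, "classification_scheme"))
  if (any(abs(w) > scheme$limit))
    stop("weight outside the classification range [-",
         scheme$limit, ", ", scheme$limit, "]")
  eps <- scheme$epsilon
  b <- scheme$strong_boundary
  lab <- ifelse(w < -b, "strong inhibitory",
         ifelse(w < -eps, "weak inhibitory",
         ifelse(w <= eps, "unconnected",
         ifelse(w <= b, "weak excitatory", "strong excitatory"))))
  factor(lab, levels = scheme$levels)
}

#' Per-class classification accuracy of derived weights
#'
#' For each actual connection class, the fraction of its members whose
#' derived weight falls in the same class. Classes with no members are
#' reported as `NA`.
#'
#' @param derived,actual weight vectors of equal length.
#' @param scheme a [classification_scheme()]; derived weights are clipped
#'   into its range before classification (training does not bound them).
#' @return Named numeric vector, one entry per class.
#' @export
classification_accuracy <- function(derived, actual,
                                    scheme = classification_scheme()) {
  if (length(derived) != length(actual))
    stop("derived and actual must have equal length")
  dcls <- classify_weights(pmin(pmax(derived, -scheme$limit),
                                scheme$limit), scheme)
  acls <- classify_weights(actual, scheme)
  vapply(scheme$levels, function(lv) {
    in_class <- acls == lv
    if (!any(in_class)) NA_real_ else mean(dcls[in_class] == lv)
  }, 1)
}

#' Calibrate the unconnected dead-zone half-width
#'
#' Pools, over runs whose spike-prediction performance exceeds the
#' threshold, the squared errors of derived weights for neurons that are
#' actually unconnected, and returns the pooled RMSE. This is the
#' data-driven origin of the classification scheme's `epsilon`.
#'
#' @param runs list of runs, each a list with elements `derived`, `actual`
#'   and `performance`.
#' @param performance_threshold qualifying performance (default 0.99).
#' @return Pooled RMSE in mV.
#' @export
calibrate_epsilon <- function(runs, performance_threshold = 0.99) {
  qual <- Filter(function(r) isTRUE(r$performance > performance_threshold),
                 runs)
  if (length(qual) == 0)
    stop("no run with performance > ", performance_threshold, call. = FALSE)
  sq <- unlist(lapply(qual, function(r) {
    un <- which(r$actual == 0)
    (r$derived[un] - r$actual[un])^2
  }))
  if (length(sq) == 0)
    stop("no actually-unconnected neuron in qualifying runs", call. = FALSE)
  sqrt(mean(sq))
}

#' Cluster weights into subpopulations by magnitude
#'
#' One-dimensional agglomerative clustering (complete-linkage [hclust()])
#' of weight magnitudes, run separately within each sign, into `n_groups`
#' ordered groups; positive and negative weights never share a group.
#' With the default three groups the labels are weak/mid/strong crossed
#' with excitatory/inhibitory. Zero weights are unconnected and get `NA`.
#'
#' @param weights numeric weights.
#' @param n_groups groups per sign (default 3); each sign present must
#'   offer at least `n_groups` distinct magnitudes.
#' @return Character vector of group labels aligned with `weights`.
#' @export
#' @examples
#' cluster_subpopulations(c(1, 1.1, 4, 4.1, 7, 7.1))
cluster_subpopulations <- function(weights, n_groups = 3) {
  if (n_groups < 1) stop_field("n_groups", "must be >= 1")
  grade <- if (n_groups == 3) c("weak", "mid", "strong") else
    paste0("g", seq_len(n_groups))
  labels <- rep(NA_character_, length(weights))
  for (s in c(1, -1)) {
    sel <- which(sign(weights) == s)
    if (length(sel) == 0) next
    mag <- abs(weights[sel])
    if (length(unique(mag)) < n_groups)
      stop("fewer than ", n_groups, " distinct magnitudes for the ",
           if (s > 0) "excitatory" else "inhibitory",
           " sign: no separation", call. = FALSE)
    grp <- cutree(hclust(dist(mag), method = "complete"), k = n_groups)
    ord <- rank(tapply(mag, grp, mean))  # order groups by mean magnitude
    labels[sel] <- paste(grade[ord[grp]],
                         if (s > 0) "excitatory" else "inhibitory")
  }
  labels
}

#' Evaluate one derivation run
#'
#' Bundles the weight-recovery and spike-prediction measures for a single
#' (derived, actual) pair into one report: RMSE, Pearson correlation,
#' TPR/PPV/performance (when spike trains are given), and per-class RMSE
#' and classification accuracy.
#'
#' @param derived,actual weight vectors of equal length.
#' @param actual_spikes,predicted_spikes optional binary spike trains for
#'   the prediction scores.
#' @param scheme a [classification_scheme()].
#' @return An object of class `"evaluation_report"` (a list).
#' @export
evaluate_run <- function(derived, actual, actual_spikes = NULL,
                         predicted_spikes = NULL,
                         scheme = classification_scheme()) {
  acls <- classify_weights(actual, scheme)
  per_class_rmse <- vapply(scheme$levels, function(lv) {
    sel <- which(acls == lv)
    if (length(sel) == 0) NA_real_ else weight_rmse(derived, actual, sel)
  }, 1)
  rep <- list(rmse_weights = weight_rmse(derived, actual),
              pearson_r = cor(derived, actual),
              per_class_rmse = per_class_rmse,
              per_class_accuracy = classification_accuracy(derived, actual,
                                                           scheme))
  if (!is.null(actual_spikes) && !is.null(predicted_spikes))
    rep <- c(rep, spike_prediction_scores(actual_spikes, predicted_spikes))
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Weight RMSE %.4g mV, Pearson r %.3f\n",
              x$rmse_weights, x$pearson_r))
  if (!is.null(x$tpr))
    cat(sprintf("Spike prediction: TPR %.3f, PPV %.3f, performance %.3f\n",
                x$tpr, x$ppv, x$performance))
  cat("Per-class accuracy:\n")
  print(round(x$per_class_accuracy, 3))
  invisible(x)
}
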