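#' Leaky integrate-and-fire parameters
#'
#' Membrane dynamics follow the explicit Euler update
#' \deqn{V_m(t+\Delta t) = V_m(t) + \Delta t \,
#'   \frac{-(V_m(t) - V_e) + I_m R_m}{\tau_m}}
#' with a strict threshold-and-reset mechanism: if the updated potential
#' exceeds `V_t` the neuron spikes and the potential is set to `V_reset`.
#' The membrane current is assembled from presynaptic spikes as
#' \eqn{I_m = I_{post} \sum_i w_i \, spike_i}, with weights acting as
#' dimensionless multipliers of the unit postsynaptic current.
#'
#' `V_t` and `V_reset` default to standard values (-55 mV and the resting
#' potential) consistent with the other constants; they are not derived
#' quantities and can be overridden freely.
#'
#' @param V_e resting potential, mV (default -75).
#' @param C_m membrane capacitance, pF (default 100).
#' @param R_m input resistance, MOhm (default 10); with the defaults
#'   `tau_m = C_m * R_m = 1` ms.
#' @param I_post unit postsynaptic current, nA (default 1).
#' @param V_t spike threshold, mV (default -55).
#' @param V_reset post-spike reset potential, mV (default `V_e`).
#' @param dt integration step, ms (default 1).
#' @return An object of class `"lif_params"`; `tau_m` (ms) is computed as
#'   `C_m * R_m / 1000` with C_m in pF and R_m in MOhm.
#' @export
#' @examples
#' lif_params()
lif_params <- function(V_e = -75, C_m = 100, R_m = 10, I_post = 1,
                       V_t = -55, V_reset = V_e, dt = 1) {
  tau_m <- C_m * R_m / 1000  # pF * MOhm = us; /1000 -> ms
  if (dt <= 0) stop_field("dt", "must be > 0")
  if (V_reset > V_t) stop_field("V_reset", "must not exceed V_t")
  if (tau_m <= 0) stop_field("C_m", "C_m * R_m must be > 0")
  structure(list(V_e = V_e, C_m = C_m, R_m = R_m, tau_m = tau_m,
                 I_post = I_post, V_t = V_t, V_reset = V_reset, dt = dt),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf("LIF: V_e=%g mV, tau_m=%g ms (C_m=%g pF, R_m=%g MOhm), V_t=%g mV, V_reset=%g mV, I_post=%g nA, dt=%g ms\n",
              x$V_e, x$tau_m, x$C_m, x$R_m, x$V_t, x$V_reset, x$I_post, x$dt))
  invisible(x)
}

#' Memoryless threshold-unit forward model
#'
#' Per bin the membrane potential is the weighted sum of that bin's inputs,
#' \eqn{V = \sum_i x_i w_i}; the unit spikes iff `V > threshold` (strict),
#' with no memory across bins.
#'
#' @param raster presynaptic [spike_raster()].
#' @param weights per-input weights in mV; length must equal the raster's
#'   neuron count.
#' @param threshold spike threshold in mV (default 20, resting potential 0).
#' @return Integer 0/1 spike train over all bins in trial-major order.
#' @export
#' @examples
#' r <- generate_raster(population_spec(10, silent_fraction = 0), 2, 100,
#'                      seed = 1)
#' y <- threshold_forward(r, rep(5, 10))
threshold_forward <- function(raster, weights, threshold = 20) {
  stopifnot(inherits(raster, "spike_raster"))
  if (length(weights) != raster$n_neurons)
    stop("length(weights) must equal the raster's neuron count")
  csr <- raster_csr(raster)
  threshold_forward_cpp(csr$ptr, csr$idx, as.numeric(weights), threshold)
}

#' Single Euler step of the leaky integrate-and-fire model
#'
#' @param V_m current membrane potential, mV.
#' @param I_m membrane current, nA.
#' @param params a [lif_params()].
#' @return List with `V_m` (potential after the step, post-reset) and
#'   `spiked` (0/1).
#' @export
#' @examples
#' lif_step(-75, 0)           # resting fixed point
#' lif_step(-75, 2.5)$spiked  # suprathreshold drive
lif_step <- function(V_m, I_m, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"), is.finite(V_m), is.finite(I_m))
  V <- V_m + params$dt * (-(V_m - params$V_e) + I_m * params$R_m) / params$tau_m
  if (V > params$V_t) list(V_m = params$V_reset, spiked = 1L)
  else list(V_m = V, spiked = 0L)
}

#' Leaky integrate-and-fire forward model over a raster
#'
#' Assembles the membrane current per bin from the presynaptic spikes,
#' advances the Euler dynamics of [lif_params()] with threshold and reset,
#' and resets the membrane to rest at every trial boundary (trials are
#' independent).
#'
#' @inheritParams threshold_forward
#' @param params a [lif_params()]; its `dt` is overridden by the raster's
#'   bin width.
#' @param return_potential also return the per-bin membrane potential.
#' @return Integer 0/1 spike train (trial-major), or a list with `spikes`
#'   and `potential` when `return_potential = TRUE`.
#' @export
lif_forward <- function(raster, weights, params = lif_params(),
                        return_potential = FALSE) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(params, "lif_params"))
  if (length(weights) != raster$n_neurons)
    stop("length(weights) must equal the raster's neuron count")
  csr <- raster_csr(raster)
  out <- lif_forward_cpp(csr$ptr, csr$idx, as.numeric(weights),
                         raster$n_bins, params$V_e, params$R_m,
                         params$tau_m, raster$dt, params$I_post,
                         params$V_t, params$V_reset, return_potential)
  if (return_potential) out else out$spikes
}
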