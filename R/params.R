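#' Neuron-model constants for a recurrent spiking network
#'
#' Bundles every constant of the discrete-time leaky integrate-and-fire
#' (LIF) model: integration step, membrane and synaptic time constants, the
#' spike-timing tolerance `tau_star` used when filtering spikes for the
#' learning rule, the readout filter constant, threshold/rest/reset
#' potentials, and the width of the pseudo-derivative.
#'
#' Time constants are in milliseconds; potentials are dimensionless.  The
#' spike-timing tolerance `tau_star` (and any `tau` passed to
#' [filter_spikes()]) may be exactly `0`, which selects the
#' precise-spike-timing limit in which the filtered trace equals the raw
#' spike train.  Strictly negative time constants are rejected.
#'
#' @param N number of neurons.
#' @param dt integration step (ms).
#' @param tau_m membrane time constant (ms).
#' @param tau_s synaptic spike-filter time constant (ms), used for the
#'   recurrent input trace `s_hat`.
#' @param tau_star spike-timing tolerance (ms): time constant of the filter
#'   applied to spikes before computing learning errors.  `0` selects the
#'   exact spike-timing limit.
#' @param tau_ro readout filter time constant (ms).
#' @param v_th firing threshold.
#' @param v_rest rest potential.
#' @param w_res signed reset increment added to the membrane potential of a
#'   neuron at the step its spike is registered; the default `-20`
#'   hyperpolarizes the neuron after each spike.
#' @param dv width of the pseudo-derivative (surrogate gradient) bump.
#' @param zero_diag logical; if `TRUE`, training keeps the diagonal of the
#'   recurrent weight matrix (self-connections) at zero.
#'
#' @return An object of class `"network_params"` (a named list).
#' @seealso [simulate_network()], [pseudo_derivative()], [filter_spikes()]
#' @export
#' @examples
#' p <- network_params(N = 10)
#' p$tau_m
network_params <- function(N,
                           dt = 1,
                           tau_m = 8,
                           tau_s = 2,
                           tau_star = 2,
                           tau_ro = 10,
                           v_th = 0,
                           v_rest = -4,
                           w_res = -20,
                           dv = 1,
                           zero_diag = FALSE) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 1, N == round(N))
  if (dt <= 0) stop("`dt` must be > 0")
  for (nm in c("tau_m", "tau_s", "tau_ro")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || val <= 0)
      stop(sprintf("`%s` must be a positive scalar", nm))
  }
  if (tau_star < 0)
    stop("`tau_star` must be >= 0 (0 selects the exact spike-timing limit)")
  if (dv <= 0) stop("`dv` must be > 0")
  if (v_th < v_rest) stop("`v_th` must be >= `v_rest`")
  structure(
    list(N = as.integer(N), dt = dt, tau_m = tau_m, tau_s = tau_s,
         tau_star = tau_star, tau_ro = tau_ro, v_th = v_th,
         v_rest = v_rest, w_res = w_res, dv = dv,
         zero_diag = isTRUE(zero_diag)),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat("Recurrent LIF network parameters\n")
  cat(sprintf("  N = %d neurons, dt = %g ms\n", x$N, x$dt))
  cat(sprintf("  tau_m = %g, tau_s = %g, tau_star = %g, tau_ro = %g (ms)\n",
              x$tau_m, x$tau_s, x$tau_star, x$tau_ro))
  cat(sprintf("  v_th = %g, v_rest = %g, w_res = %g, dv = %g\n",
              x$v_th, x$v_rest, x$w_res, x$dv))
  invisible(x)
}

#' Initial dynamical state of the network
#'
#' All-zero spikes and traces, membrane potential at rest.  The spike
#' response variables `e` (the running estimates of the sensitivity of the
#' membrane potential to each synaptic weight) depend only on the
#' presynaptic trace, so they are stored as a single length-`N` vector; the
#' full N-by-N array is this vector broadcast across rows.
#'
#' @param params a [network_params()] object.
#' @param v optional initial membrane potentials (defaults to `v_rest`).
#' @return An object of class `"network_state"`: a list with fields `v`
#'   (membrane potentials), `s` (current binary spikes), `s_hat` (synaptic
#'   trace), `e` (spike-response / eligibility vector, length `N`) and `p`
#'   (pseudo-derivative values).
#' @export
init_state <- function(params, v = NULL) {
  N <- params$N
  if (is.null(v)) v <- rep(params$v_rest, N)
  stopifnot(length(v) == N)
  structure(
    list(v = v, s = numeric(N), s_hat = numeric(N),
         e = numeric(N), p = pseudo_derivative(v, params$dv)),
    class = "network_state"
  )
}
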