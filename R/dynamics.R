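#' Spike raster container
#'
#' A thin wrapper around an N-by-T binary matrix of spikes with its
#' integration step, the central exchange object between simulation,
#' learning and the dimensionality analyses.
#'
#' @param spikes N-by-T matrix with entries in \{0, 1\} (rows = neurons,
#'   columns = time steps).
#' @param dt integration step (ms).
#' @return An object of class `"spike_raster"`.
#' @export
spike_raster <- function(spikes, dt = 1) {
  spikes <- as.matrix(spikes)
  if (ncol(spikes) < 1) stop("a raster needs at least one time step")
  if (any(spikes != 0 & spikes != 1))
    stop("raster entries must be 0 or 1")
  structure(list(spikes = spikes, dt = dt), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons x %d steps (dt = %g ms), %d spikes\n",
              nrow(x$spikes), ncol(x$spikes), x$dt, sum(x$spikes)))
  invisible(x)
}

# accept either a spike_raster or a plain matrix
raster_matrix <- function(x) {
  if (inherits(x, "spike_raster")) x$spikes else as.matrix(x)
}

#' One step of the network dynamics
#'
#' Advances the discrete-time LIF dynamics by one step.  The update order
#' is: (i) spikes are registered from the previous membrane potential,
#' `s <- step(v_prev - v_th)`; (ii) the membrane potential integrates the
#' recurrent input through the previous synaptic trace plus the external
#' current, and neurons whose spike was just registered receive the signed
#' reset increment `w_res`; (iii) the synaptic trace and the spike-response
#' (eligibility) vector are updated; (iv) the pseudo-derivative is evaluated
#' at the new potential.
#'
#' The reset is applied at the same step the spike is registered, so a
#' single threshold crossing produces a single spike.
#'
#' @param state a [init_state()] object (fields `v`, `s`, `s_hat`, `e`, `p`).
#' @param w N-by-N recurrent weight matrix.
#' @param I_t external current, length-N vector.
#' @param params a [network_params()] object.
#' @return The next `"network_state"`.
#' @export
step_dynamics <- function(state, w, I_t, params) {
  N <- params$N
  if (length(state$v) != N || length(I_t) != N)
    stop("state/current length does not match params$N")
  if (!is.matrix(w) || nrow(w) != N || ncol(w) != N)
    stop("`w` must be an N-by-N matrix")
  if (any(!is.finite(I_t))) stop("non-finite external current")
  bm <- exp(-params$dt / params$tau_m)
  bs <- exp(-params$dt / params$tau_s)

  s_new <- as.numeric(state$v - params$v_th > 0)
  drive <- as.numeric(w %*% state$s_hat) + I_t + params$v_rest
  v_new <- bm * state$v + (1 - bm) * drive + params$w_res * s_new
  e_new <- bm * state$e + (1 - bm) * state$s_hat
  s_hat_new <- bs * state$s_hat + (1 - bs) * s_new

  structure(
    list(v = v_new, s = s_new, s_hat = s_hat_new, e = e_new,
         p = pseudo_derivative(v_new, params$dv)),
    class = "network_state"
  )
}

#' Simulate the recurrent spiking network
#'
#' Rolls the dynamics out for `T` steps from a deterministic initial state
#' (all-zero spikes and traces, membrane at rest, unless `state0` is given).
#' Optionally the full time courses of the membrane potential, synaptic
#' trace, spike-response vector and pseudo-derivative are recorded; these
#' are what the learning rules consume.
#'
#' When `clamp` is supplied the network's own spikes are replaced by the
#' given raster when driving the recurrent input, the reset and the
#' eligibility variables (teacher forcing); the recorded potentials then
#' describe the clamped trajectory.
#'
#' @param w N-by-N recurrent weight matrix.
#' @param I N-by-T matrix of external currents (or a length-N vector,
#'   recycled across time).
#' @param params a [network_params()] object.
#' @param T_steps number of steps; defaults to `ncol(I)`.
#' @param record character vector among `c("v", "s_hat", "e", "p")` naming
#'   additional traces to keep.
#' @param state0 optional initial `"network_state"`.
#' @param clamp optional N-by-T raster (or [spike_raster()]) of spikes to
#'   force.
#' @param margin robustness margin used for the prediction raster under
#'   clamping: a step counts as a predicted spike only if `v` exceeds
#'   `v_th + margin` where the clamped raster has a spike, and already
#'   counts as one if `v` exceeds `v_th - margin` where it is silent.
#'   With the default 0 the prediction is the plain threshold crossing.
#' @return A list with the [spike_raster()] `raster` and any recorded
#'   N-by-T trace matrices (`v`, `s_hat`, `e`, `p`).
#' @export
#' @examples
#' p <- network_params(N = 3)
#' out <- simulate_network(matrix(0, 3, 3), matrix(0, 3, 10), p)
#' sum(out$raster$spikes)  # silent at rest
simulate_network <- function(w, I, params, T_steps = NULL,
                             record = c("v", "s_hat", "e", "p"),
                             state0 = NULL, clamp = NULL, margin = 0) {
  N <- params$N
  if (is.null(dim(I))) I <- matrix(I, nrow = N, ncol = max(1, T_steps))
  if (is.null(T_steps)) T_steps <- ncol(I)
  if (T_steps < 1) stop("T_steps must be >= 1")
  if (nrow(I) != N || ncol(I) < T_steps)
    stop("`I` must be N-by-T with T >= T_steps")
  record <- match.arg(record, several.ok = TRUE,
                      choices = c("v", "s_hat", "e", "p"))
  if (!is.null(clamp)) {
    clamp <- raster_matrix(clamp)
    if (nrow(clamp) != N || ncol(clamp) < T_steps)
      stop("`clamp` raster must be N-by-T")
  }
  st <- if (is.null(state0)) init_state(params) else state0

  S <- matrix(0, N, T_steps)
  tr <- list()
  for (nm in record) tr[[nm]] <- matrix(0, N, T_steps)

  bm <- exp(-params$dt / params$tau_m)
  bs <- exp(-params$dt / params$tau_s)
  v <- st$v; s_hat <- st$s_hat; e <- st$e
  P <- if (!is.null(clamp)) matrix(0, N, T_steps) else NULL
  for (t in seq_len(T_steps)) {
    s_own <- if (is.null(clamp) || margin == 0) {
      as.numeric(v - params$v_th > 0)
    } else {
      as.numeric(v - params$v_th - margin * (2 * clamp[, t] - 1) > 0)
    }
    s_new <- if (is.null(clamp)) s_own else clamp[, t]
    drive <- as.numeric(w %*% s_hat) + I[, t] + params$v_rest
    v <- bm * v + (1 - bm) * drive + params$w_res * s_new
    e <- bm * e + (1 - bm) * s_hat
    s_hat <- bs * s_hat + (1 - bs) * s_new
    S[, t] <- s_new
    if (!is.null(P)) P[, t] <- s_own
    if (!is.null(tr$v)) tr$v[, t] <- v
    if (!is.null(tr$s_hat)) tr$s_hat[, t] <- s_hat
    if (!is.null(tr$e)) tr$e[, t] <- e
    if (!is.null(tr$p)) tr$p[, t] <- pseudo_derivative(v, params$dv)
  }
  out <- c(list(raster = spike_raster(S, params$dt)), tr)
  # under clamping, also expose the spikes the network would have emitted
  # one step ahead along the clamped trajectory
  if (!is.null(P)) out$prediction <- spike_raster(P, params$dt)
  out
}

#' Exponentially filter a spike raster
#'
#' Applies the first-order low-pass filter
#' `x_t = exp(-dt/tau) x_{t-1} + (1 - exp(-dt/tau)) s_t` column by column,
#' starting from zero.  With `tau = 0` the filter degenerates to the
#' identity: the filtered trace equals the raw spike train (the exact
#' spike-timing limit).
#'
#' @param raster a [spike_raster()] or any N-by-T numeric matrix.
#' @param tau filter time constant (ms); `0` returns the input unchanged.
#' @param dt integration step (ms); defaults to the raster's own `dt` or 1.
#' @return An N-by-T numeric matrix.
#' @export
filter_spikes <- function(raster, tau, dt = NULL) {
  if (is.null(dt)) dt <- if (inherits(raster, "spike_raster")) raster$dt else 1
  S <- raster_matrix(raster)
  if (tau < 0) stop("`tau` must be >= 0")
  if (tau == 0) return(S)
  b <- exp(-dt / tau)
  out <- S * (1 - b)
  for (t in seq_len(ncol(S))[-1]) {
    out[, t] <- b * out[, t - 1] + out[, t]
  }
  out
}

#' Pseudo-derivative of the spike nonlinearity
#'
#' Surrogate for the derivative of the hard threshold, a bump of width `dv`
#' peaking at `v = 0` (the firing threshold) with height `1/(4 dv)`:
#' `p(v) = exp(v/dv) / (dv (exp(v/dv) + 1)^2)`.  Evaluated through the
#' symmetric form `sech^2(v/(2 dv)) / (4 dv)` so that large `|v|/dv` cannot
#' overflow.
#'
#' @param v membrane potentials (relative to the threshold at 0).
#' @param dv width parameter, `> 0`.
#' @return Pseudo-derivative values, same shape as `v`.
#' @export
#' @examples
#' pseudo_derivative(0, dv = 0.2)  # 1/(4 * 0.2) = 1.25
pseudo_derivative <- function(v, dv) {
  if (!is.numeric(dv) || length(dv) != 1 || dv <= 0)
    stop("`dv` must be a positive scalar")
  # sech^2 form: exp(x)/(exp(x)+1)^2 = 1/(4 cosh^2(x/2))
  x <- v / (2 * dv)
  (1 / (4 * dv)) / cosh(x)^2
}

#' Update the spike-response (eligibility) vector
#'
#' One step of the recursion for the sensitivity of the membrane potential
#' to the recurrent weights.  Because the sensitivity of `v_i` to `w_ij`
#' depends only on the presynaptic trace `s_hat_j`, all rows of the N-by-N
#' sensitivity array are identical and it is stored as a length-N vector
#' indexed by the presynaptic neuron.
#'
#' @param e current spike-response vector (length N) or N-by-N matrix with
#'   identical rows.
#' @param s_hat presynaptic synaptic trace at the previous step (length N).
#' @param params a [network_params()] object.
#' @return Updated spike response, same shape as `e`.
#' @export
update_spike_response <- function(e, s_hat, params) {
  bm <- exp(-params$dt / params$tau_m)
  if (is.matrix(e)) {
    sweep(bm * e, 2, (1 - bm) * s_hat, "+")
  } else {
    bm * e + (1 - bm) * s_hat
  }
}
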