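#' Specification of the store-and-recall task
#'
#' The network is prompted with a clock-like input and must autonomously
#' reproduce a target trajectory of `O` continuous channels, each a
#' superposition of sinusoids at the fixed frequencies 1, 2, 3 and 5 Hz
#' with random amplitudes and phases.
#'
#' @param O number of output channels.
#' @param C number of clock channels; channel `c` is active during the
#'   `c`-th contiguous fraction of the episode.
#' @param T_steps episode length in integration steps.
#' @param freqs sinusoid frequencies (Hz).
#' @param amp_range range of the uniform amplitude draw.
#' @param phase_range range of the uniform phase draw (radians).
#' @param sigma_inp scale of the Gaussian input projection entries.
#' @param seed integer seed for amplitudes, phases and the projection.
#' @return An object of class `"store_recall_spec"`.
#' @export
store_recall_spec <- function(O = 3, C = 5, T_steps = 200,
                              freqs = c(1, 2, 3, 5),
                              amp_range = c(0.5, 2.0),
                              phase_range = c(0, 2 * pi),
                              sigma_inp = 10, seed = 1) {
  stopifnot(O >= 1, C >= 1, T_steps >= C, sigma_inp > 0)
  structure(list(O = as.integer(O), C = as.integer(C),
                 T_steps = as.integer(T_steps), freqs = freqs,
                 amp_range = amp_range, phase_range = phase_range,
                 sigma_inp = sigma_inp, seed = as.integer(seed)),
            class = "store_recall_spec")
}

#' Generate a store-and-recall episode
#'
#' Draws the target trajectory
#' `y_star[k, t] = sum_f A[k, f] * sin(2 pi f t + phi[k, f])` (amplitudes
#' uniform in `amp_range`, phases uniform in `phase_range`, time in
#' seconds) and the clock input: `C` binary channels tiling the episode,
#' projected into the network by an N-by-C Gaussian matrix `J_inp` with
#' scale `sigma_inp`.
#'
#' @param spec a [store_recall_spec()].
#' @param N number of neurons.
#' @param dt integration step (ms).
#' @return A list with `input` (N-by-T current matrix), `y_star` (O-by-T),
#'   `clock` (C-by-T), `J_inp`, `A`, `phi` and the `spec`.
#' @export
make_store_recall <- function(spec, N, dt = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  O <- spec$O; C <- spec$C; Tn <- spec$T_steps
  nf <- length(spec$freqs)
  A <- matrix(stats::runif(O * nf, spec$amp_range[1], spec$amp_range[2]),
              O, nf)
  phi <- matrix(stats::runif(O * nf, spec$phase_range[1],
                             spec$phase_range[2]), O, nf)
  tt <- (seq_len(Tn) - 1) * dt / 1000  # seconds
  y_star <- matrix(0, O, Tn)
  for (k in seq_len(O)) {
    for (fi in seq_len(nf)) {
      y_star[k, ] <- y_star[k, ] +
        A[k, fi] * sin(2 * pi * spec$freqs[fi] * tt + phi[k, fi])
    }
  }
  clock <- matrix(0, C, Tn)
  edges <- floor(seq(0, Tn, length.out = C + 1))
  for (cc in seq_len(C)) {
    clock[cc, (edges[cc] + 1):edges[cc + 1]] <- 1
  }
  J_inp <- matrix(stats::rnorm(N * C, sd = spec$sigma_inp), N, C)
  list(input = J_inp %*% clock, y_star = y_star, clock = clock,
       J_inp = J_inp, A = A, phi = phi, spec = spec)
}

#' Set up and train a network on store-and-recall
#'
#' End-to-end driver for the benchmark: generates the episode, builds the
#' internal spike target from the untrained network, pre-trains the
#' readout (the readout-limit fit), expands it to rank `R`, builds the
#' feedback matrix, and trains the recurrent weights.  The readout is
#' frozen during recurrent training; the per-epoch MSE is measured through
#' it on the spike train filtered at the spike-timing tolerance
#' `params$tau_star`, matching the filter used by the learning rule.
#'
#' @param spec a [store_recall_spec()].
#' @param params a [network_params()].
#' @param R feedback rank.
#' @param config a [learning_config()].
#' @param feedback_mode passed to [build_feedback()]; `"from_readout"`
#'   (default) uses `D = B_plus^T B_plus`, `"diagonal"` the
#'   Kronecker-delta construction.
#' @param seed master seed for the projection, readout expansion and
#'   weight initialization (child seeds via [derive_seed()]).
#' @param replica_seed optional separate seed for the initial recurrent
#'   weights (and training noise): training replicas share the task,
#'   internal target and readout (all governed by `seed`) and differ only
#'   in this seed.
#' @param sigma_w scale of the initial recurrent weights.
#' @param readout_epochs,readout_lr budget for the readout pre-training.
#' @param record_rasters keep per-epoch rasters (for the dimensionality
#'   analyses).
#' @return A list with the `"training_log"` `log`, plus `task`, `bundle`,
#'   `feedback`, `readout`, `params`, and the target raster `s_star`.
#' @export
run_store_recall <- function(spec, params, R,
                             config = learning_config(),
                             feedback_mode = c("from_readout", "diagonal",
                                               "random_gaussian"),
                             seed = 1, replica_seed = NULL, sigma_w = 1,
                             readout_epochs = 2000, readout_lr = 1e-2,
                             record_rasters = FALSE) {
  feedback_mode <- match.arg(feedback_mode)
  N <- params$N
  task <- make_store_recall(spec, N, params$dt)
  tgt <- generate_target_spikes(task$y_star, task$input, params,
                                seed = derive_seed(seed, 1))
  s_bar_star <- filter_spikes(tgt$raster$spikes, params$tau_star, params$dt)
  ro <- train_readout(s_bar_star, task$y_star, lr = readout_lr,
                      epochs = readout_epochs)
  ro$tau <- params$tau_star
  Bp <- expand_readout(ro, R, seed = derive_seed(seed, 2))
  fb <- build_feedback(feedback_mode, R, N, B_plus = Bp,
                       seed = derive_seed(seed, 3))
  bundle <- make_generalized_target(Bp, tgt$raster, task$y_star,
                                    params$tau_star, params$dt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (is.null(replica_seed)) replica_seed <- derive_seed(seed, 4)
  set.seed(replica_seed)
  w0 <- init_weights(N, sigma_w, params$zero_diag)
  log <- train_network(w0, task$input, bundle, fb, config, params,
                       readout = ro, record_rasters = record_rasters)
  list(log = log, task = task, bundle = bundle, feedback = fb,
       readout = ro, params = params, s_star = tgt$raster)
}
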