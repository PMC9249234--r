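#' Training configuration
#'
#' @param eta learning rate for the recurrent weights.
#' @param eta_ro learning rate for the readout (when it is refined during
#'   training).
#' @param epochs number of training epochs.
#' @param rule which form of the weight update to use: `"target_form"`
#'   (feedback matrix `D` applied to filtered spike errors),
#'   `"error_form"` (expanded readout applied to generalized output
#'   errors), or `"ltts"` (purely local target-spike rule, the `D = I`
#'   limit).
#' @param clamped logical; if `TRUE` the eligibility and pseudo-derivative
#'   factors are computed along the clamped trajectory in which the target
#'   spikes replace the network's own (only admissible at full rank
#'   `R = N`).
#' @param optimizer `"sgd"` for plain gradient steps of size `eta`, or
#'   `"adam"`.
#' @param schedule `"epoch"` applies the accumulated update once per
#'   episode (the rules are written as full-episode sums); `"step"`
#'   applies each rank-one increment online during the rollout.
#' @param margin robustness margin for the spike-level error: a target
#'   spike only counts as achieved once the membrane clears
#'   `v_th + margin`, and a silent step once it stays below
#'   `v_th - margin`, evaluated along the teacher-forced trajectory for
#'   the clamped rule and along the free-running trajectory otherwise.
#'   A positive margin makes the learned pattern robust to small
#'   perturbations; 0 reproduces the plain rules.
#' @param epsilon standard deviation of white synaptic noise added to every
#'   weight at every epoch (the single-trial dimensionality probe); `0`
#'   disables it.
#' @param train_readout logical; refine the readout concurrently (Adam,
#'   `eta_ro`) instead of keeping it frozen.
#' @return An object of class `"learning_config"`.
#' @export
learning_config <- function(eta = 0.05, eta_ro = 0.01, epochs = 100,
                            rule = c("target_form", "error_form", "ltts"),
                            clamped = FALSE,
                            optimizer = c("sgd", "adam"),
                            schedule = c("epoch", "step"),
                            margin = 0,
                            epsilon = 0,
                            train_readout = FALSE) {
  stopifnot(eta >= 0, epochs >= 1, epsilon >= 0, margin >= 0)
  structure(list(eta = eta, eta_ro = eta_ro, epochs = as.integer(epochs),
                 rule = match.arg(rule), clamped = isTRUE(clamped),
                 optimizer = match.arg(optimizer),
                 schedule = match.arg(schedule),
                 margin = margin,
                 epsilon = epsilon,
                 train_readout = isTRUE(train_readout)),
            class = "learning_config")
}

# shared shape check for the three update rules
check_series <- function(p, e, ...) {
  Ts <- vapply(list(p, e, ...), ncol, integer(1))
  if (length(unique(Ts)) != 1)
    stop("all time series passed to a weight-update rule must share T")
  Ts[1]
}

#' Weight update, error-propagating form
#'
#' `dw[i, j] = eta * sum_t sum_k B_plus[k, i] *
#'   (Y_star[k, t+1] - Y[k, t+1]) * p[i, t] * e[j, t]`:
#' the R generalized output errors are projected back through the expanded
#' readout and gated by the postsynaptic pseudo-derivative and the
#' presynaptic spike response.
#'
#' @param B_plus an [expand_readout()] object or R-by-N matrix.
#' @param Y_star,Y R-by-T generalized target and network output
#'   (`Y = B_plus %*% s_bar`).
#' @param p N-by-T pseudo-derivative trace.
#' @param e N-by-T spike-response trace (presynaptic index).
#' @param eta learning rate.
#' @return N-by-N weight increment.
#' @export
delta_w_error_form <- function(B_plus, Y_star, Y, p, e, eta = 1) {
  Bp <- if (inherits(B_plus, "expanded_readout")) B_plus$B_plus else B_plus
  Tn <- check_series(p, e, Y_star, Y)
  if (Tn < 2) return(matrix(0, nrow(p), nrow(p)))
  err <- t(Bp) %*% (Y_star - Y)             # N x T, back-projected error
  idx <- seq_len(Tn - 1)
  eta * ((err[, idx + 1, drop = FALSE] * p[, idx, drop = FALSE]) %*%
           t(e[, idx, drop = FALSE]))
}

#' Weight update, target-propagating form
#'
#' `dw[i, j] = eta * sum_t sum_k D[i, k] *
#'   (s_bar_star[k, t+1] - s_bar[k, t+1]) * p[i, t] * e[j, t]`:
#' the filtered spike errors are mixed through the feedback matrix `D`.
#' With `D = B_plus^T B_plus` and `Y_star = B_plus s_bar_star` this is
#' algebraically identical to [delta_w_error_form()]; with `D = I` it
#' reduces to [delta_w_ltts()].
#'
#' @param D N-by-N feedback matrix or a [build_feedback()] object.
#' @param s_bar_star,s_bar N-by-T filtered target and network spike traces.
#' @inheritParams delta_w_error_form
#' @return N-by-N weight increment.
#' @export
delta_w_target_form <- function(D, s_bar_star, s_bar, p, e, eta = 1) {
  Dm <- if (inherits(D, "feedback_spec")) D$D else D
  Tn <- check_series(p, e, s_bar_star, s_bar)
  if (Tn < 2) return(matrix(0, nrow(p), nrow(p)))
  err <- Dm %*% (s_bar_star - s_bar)
  idx <- seq_len(Tn - 1)
  eta * ((err[, idx + 1, drop = FALSE] * p[, idx, drop = FALSE]) %*%
           t(e[, idx, drop = FALSE]))
}

#' Weight update, local target-spike limit
#'
#' `dw[i, j] = eta * sum_t (s_bar_star[i, t+1] - s_bar[i, t+1]) *
#' p[i, t] * e[j, t]`.  Only the postsynaptic neuron's own error enters,
#' making the rule local; it is the full-rank limit of
#' [delta_w_target_form()] with an identity feedback matrix.
#'
#' @inheritParams delta_w_target_form
#' @return N-by-N weight increment.
#' @export
delta_w_ltts <- function(s_bar_star, s_bar, p, e, eta = 1) {
  Tn <- check_series(p, e, s_bar_star, s_bar)
  if (Tn < 2) return(matrix(0, nrow(p), nrow(p)))
  err <- s_bar_star - s_bar
  idx <- seq_len(Tn - 1)
  eta * ((err[, idx + 1, drop = FALSE] * p[, idx, drop = FALSE]) %*%
           t(e[, idx, drop = FALSE]))
}

#' Spike error between two rasters
#'
#' Total number of mismatched spikes, `sum |s_star - s|`, an integer when
#' both rasters are binary.
#'
#' @param s_star,s rasters ([spike_raster()] or N-by-T matrices).
#' @return A non-negative number.
#' @export
spike_error <- function(s_star, s) {
  a <- raster_matrix(s_star); b <- raster_matrix(s)
  if (!all(dim(a) == dim(b))) stop("rasters must share dimensions")
  sum(abs(a - b))
}

#' Epochs needed to halve the initial output error
#'
#' Scans a per-epoch error series for the first epoch at which the error
#' falls to half its initial value or below.
#'
#' @param mse_per_epoch numeric vector of per-epoch output errors.
#' @return The first such epoch index, or `NA_integer_` if the error is
#'   never halved ("not reached").
#' @export
convergence_time <- function(mse_per_epoch) {
  if (length(mse_per_epoch) == 0) return(NA_integer_)
  hit <- which(mse_per_epoch <= mse_per_epoch[1] / 2)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Add a plain or noise-perturbed weight update
#'
#' `w' = w + dw + epsilon * xi`, with `xi` i.i.d. standard normal per
#' synapse.  The synaptic noise (amplitude `epsilon`) is the probe used by
#' the single-trial dimensionality estimator: after learning has
#' converged, the noise explores the space of internal solutions.
#'
#' @param w,dw N-by-N weight matrix and update.
#' @param epsilon noise amplitude (`0` for a plain update).
#' @return The updated weight matrix.  Draws from the current RNG stream
#'   when `epsilon > 0`.
#' @export
noisy_train_step <- function(w, dw, epsilon = 0) {
  stopifnot(all(dim(w) == dim(dw)), epsilon >= 0)
  w <- w + dw
  if (epsilon > 0)
    w <- w + matrix(stats::rnorm(length(w), sd = epsilon), nrow(w))
  w
}

# network output through a readout: y = B %*% filter(spikes, tau)
readout_output <- function(readout, raster, dt) {
  B <- readout$B
  tau <- readout$tau
  if (is.na(tau)) stop("readout has no filter constant `tau` set")
  B %*% filter_spikes(raster_matrix(raster), tau, dt)
}

#' One training epoch
#'
#' Simulates one full episode with the current weights, computes the
#' weight update under the configured rule, applies it once (batch
#' schedule) or step-by-step (online schedule), and returns the updated
#' weights together with the epoch's metrics: output MSE through the
#' readout (when one is supplied) and the spike error against the internal
#' target.
#'
#' In the clamped variant the pseudo-derivative and spike-response factors
#' are taken from a second, teacher-forced pass in which the target raster
#' replaces the network's own spikes; this is only admissible at full rank
#' (`feedback$R == N`) and is rejected otherwise.
#'
#' @param w N-by-N recurrent weights.
#' @param task_input N-by-T external currents.
#' @param bundle a [make_generalized_target()] target bundle.
#' @param feedback a [build_feedback()] object.
#' @param config a [learning_config()].
#' @param params a [network_params()].
#' @param readout optional [train_readout()] readout (with its `tau` field
#'   set) used for the MSE metric.
#' @param opt optional Adam state (for `optimizer = "adam"`), threaded
#'   through successive calls.
#' @return A list with `w`, `mse`, `spike_err`, `raster`, `opt`.
#' @export
train_epoch <- function(w, task_input, bundle, feedback, config, params,
                        readout = NULL, opt = NULL) {
  N <- params$N
  T_steps <- ncol(bundle$s_star)
  if (config$clamped && feedback$R < N)
    stop("the clamped rule is only admissible at full rank (R = N)")

  if (config$schedule == "step") {
    if (config$clamped)
      stop("the clamped variant is only available with the epoch schedule")
    return(train_epoch_online(w, task_input, bundle, feedback, config,
                              params, readout))
  }

  sim <- simulate_network(w, task_input, params,
                          record = c("p", "e", "v"))
  s_bar <- filter_spikes(sim$raster$spikes, bundle$tau_star, params$dt)

  if (config$clamped) {
    # teacher forcing: eligibility/pseudo-derivative factors and the
    # network's own (predicted) spikes are taken along the trajectory in
    # which the target raster replaces the emitted spikes
    cl <- simulate_network(w, task_input, params, record = c("p", "e"),
                           clamp = bundle$s_star, margin = config$margin)
    p_tr <- cl$p; e_tr <- cl$e
    s_bar_rule <- filter_spikes(cl$prediction$spikes, bundle$tau_star,
                                params$dt)
  } else {
    p_tr <- sim$p; e_tr <- sim$e
    s_bar_rule <- s_bar
    if (config$margin > 0) {
      # margin-shifted registration along the free trajectory: a target
      # spike only counts as achieved once v clears v_th + margin, a
      # silent step only once v stays below v_th - margin, so the error
      # keeps shaping weights until the solution is robust
      v_prev <- cbind(rep(params$v_rest, params$N),
                      sim$v[, -T_steps, drop = FALSE])
      shift <- params$v_th + config$margin * (2 * bundle$s_star - 1)
      s_marg <- (v_prev - shift > 0) * 1
      s_bar_rule <- filter_spikes(s_marg, bundle$tau_star, params$dt)
    }
  }

  dw <- switch(config$rule,
    target_form = delta_w_target_form(feedback, bundle$s_bar_star,
                                      s_bar_rule, p_tr, e_tr, config$eta),
    error_form = {
      if (is.null(feedback$B_plus))
        stop("`error_form` requires a feedback built from an expanded readout")
      Bp <- feedback$B_plus$B_plus
      delta_w_error_form(Bp, bundle$Y_star, Bp %*% s_bar_rule, p_tr, e_tr,
                         config$eta)
    },
    ltts = delta_w_ltts(bundle$s_bar_star, s_bar_rule, p_tr, e_tr,
                        config$eta)
  )

  if (config$optimizer == "adam") {
    if (is.null(opt)) opt <- adam_init(dim(w), lr = config$eta)
    upd <- adam_step(opt, -dw / config$eta)  # dw already carries eta
    opt <- upd$opt
    dw <- -upd$delta
  }
  if (params$zero_diag) diag(dw) <- 0
  w_new <- noisy_train_step(w, dw, config$epsilon)
  if (params$zero_diag) diag(w_new) <- 0

  mse <- NA_real_
  if (!is.null(readout)) {
    y <- readout_output(readout, sim$raster, params$dt)
    mse <- mean((bundle$y_star - y)^2)
  }
  list(w = w_new, mse = mse,
       spike_err = spike_error(bundle$s_star, sim$raster),
       raster = sim$raster, opt = opt)
}

# Online (per-step) variant of train_epoch: each rank-one increment of the
# episode sum is applied as soon as its error factor is available, so later
# steps of the same episode already run with updated weights.  Plain
# gradient steps only.
train_epoch_online <- function(w, task_input, bundle, feedback, config,
                               params, readout = NULL) {
  N <- params$N
  T_steps <- ncol(bundle$s_star)
  bm <- exp(-params$dt / params$tau_m)
  bs <- exp(-params$dt / params$tau_s)
  bstar <- if (bundle$tau_star == 0) 0 else exp(-params$dt / bundle$tau_star)
  Dm <- feedback$D
  Bp <- if (!is.null(feedback$B_plus)) feedback$B_plus$B_plus else NULL
  if (config$rule == "error_form" && is.null(Bp))
    stop("`error_form` requires a feedback built from an expanded readout")

  v <- rep(params$v_rest, N)
  s_hat <- e <- s_bar <- numeric(N)
  p_prev <- pseudo_derivative(v, params$dv)
  e_prev <- numeric(N)
  S <- matrix(0, N, T_steps)
  for (t in seq_len(T_steps)) {
    s_new <- as.numeric(v - params$v_th > 0)
    drive <- as.numeric(w %*% s_hat) + task_input[, t] + params$v_rest
    v <- bm * v + (1 - bm) * drive + params$w_res * s_new
    e <- bm * e + (1 - bm) * s_hat
    s_hat <- bs * s_hat + (1 - bs) * s_new
    s_bar <- bstar * s_bar + (1 - bstar) * s_new
    S[, t] <- s_new
    err <- switch(config$rule,
      target_form = as.numeric(Dm %*% (bundle$s_bar_star[, t] - s_bar)),
      error_form = as.numeric(
        t(Bp) %*% (bundle$Y_star[, t] - Bp %*% s_bar)),
      ltts = bundle$s_bar_star[, t] - s_bar)
    if (t >= 2) {
      dw <- config$eta * outer(err * p_prev, e_prev)
      if (params$zero_diag) diag(dw) <- 0
      w <- w + dw
    }
    p_prev <- pseudo_derivative(v, params$dv)
    e_prev <- e
  }
  w <- noisy_train_step(w, matrix(0, N, N), config$epsilon)
  if (params$zero_diag) diag(w) <- 0
  raster <- spike_raster(S, params$dt)
  mse <- NA_real_
  if (!is.null(readout)) {
    y <- readout_output(readout, raster, params$dt)
    mse <- mean((bundle$y_star - y)^2)
  }
  list(w = w, mse = mse, spike_err = spike_error(bundle$s_star, raster),
       raster = raster, opt = NULL)
}

#' Train a recurrent spiking network on a fixed episode
#'
#' Repeats [train_epoch()] for `config$epochs` epochs, tracking the output
#' MSE and spike error, and optionally snapshots of the weights and spike
#' rasters (points of the learning trajectory, consumed by the
#' dimensionality analyses).
#'
#' Metrics for epoch `n` are measured on the rollout performed *with* the
#' weights as of the start of epoch `n`, so epoch 1 reports the untrained
#' performance.
#'
#' @inheritParams train_epoch
#' @param w0 initial weights.
#' @param record_rasters logical; keep the per-epoch rasters.
#' @param record_weights logical; keep per-epoch weight snapshots.
#' @return An object of class `"training_log"`: list with `mse`,
#'   `spike_err` (length-`epochs` vectors), `w` (final weights), `raster`
#'   (final epoch's raster), `readout` (possibly refined), and optional
#'   `rasters` / `weights` lists.
#' @export
train_network <- function(w0, task_input, bundle, feedback, config, params,
                          readout = NULL,
                          record_rasters = FALSE, record_weights = FALSE) {
  w <- w0
  E <- config$epochs
  mse <- numeric(E); se <- numeric(E)
  rasters <- if (record_rasters) vector("list", E) else NULL
  weights <- if (record_weights) vector("list", E) else NULL
  opt <- NULL; opt_ro <- NULL
  for (n in seq_len(E)) {
    res <- train_epoch(w, task_input, bundle, feedback, config, params,
                       readout = readout, opt = opt)
    opt <- res$opt
    mse[n] <- res$mse
    se[n] <- res$spike_err
    if (record_rasters) rasters[[n]] <- res$raster$spikes
    if (record_weights) weights[[n]] <- res$w
    if (config$train_readout && !is.null(readout)) {
      X <- filter_spikes(res$raster$spikes, readout$tau, params$dt)
      G <- -2 * ((bundle$y_star - readout$B %*% X) %*% t(X)) / ncol(X)
      if (is.null(opt_ro)) opt_ro <- adam_init(dim(readout$B),
                                               lr = config$eta_ro)
      upd <- adam_step(opt_ro, G)
      opt_ro <- upd$opt
      readout$B <- readout$B - upd$delta
    }
    w <- res$w
  }
  structure(list(mse = mse, spike_err = se, w = w,
                 raster = res$raster, readout = readout,
                 rasters = rasters, weights = weights,
                 config = config),
            class = "training_log")
}

#' @export
print.training_log <- function(x, ...) {
  E <- length(x$mse)
  cat(sprintf("training_log: %d epochs\n", E))
  cat(sprintf("  MSE: %.4g -> %.4g | spike error: %g -> %g\n",
              x$mse[1], x$mse[E], x$spike_err[1], x$spike_err[E]))
  tc <- convergence_time(x$mse)
  cat(sprintf("  epochs to halve initial MSE: %s\n",
              ifelse(is.na(tc), "not reached", tc)))
  invisible(x)
}

#' Random initial recurrent weights
#'
#' Gaussian, zero mean, standard deviation `sigma_w / sqrt(N)`.  Draws from
#' the current RNG stream.
#'
#' @param N number of neurons.
#' @param sigma_w overall scale.
#' @param zero_diag zero the self-connections.
#' @return An N-by-N matrix.
#' @export
init_weights <- function(N, sigma_w = 1, zero_diag = FALSE) {
  w <- matrix(stats::rnorm(N * N, sd = sigma_w / sqrt(N)), N, N)
  if (zero_diag) diag(w) <- 0
  w
}
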